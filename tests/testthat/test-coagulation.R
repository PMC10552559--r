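p_default <- default_parameters()

test_that("reduced model registry: 12 coagulation species, 5 platelet-side equations", {
  reg <- register_reduced_model(p_default)
  sc <- species_counts(reg)
  expect_equal(sc$coagulation, 12L)
  expect_equal(sc$platelet, 4L)
  expect_equal(sc$platelet_side_adr, 5L)   # 4 platelet species + ADP
  cats <- vapply(reg$species, `[[`, "", "category")
  expect_equal(sum(cats == "seBound"), 1L)
  expect_equal(sum(cats == "pltBound"), 3L)
  ## seBound and pltBound species are never transported
  tr <- vapply(reg$species, `[[`, TRUE, "transported")
  expect_true(all(!tr[cats %in% c("seBound", "pltBound")]))
})

test_that("missing or negative rate constants fail fast with their names", {
  p <- p_default; p$kon1 <- NULL
  expect_error(register_reduced_model(p), "kon1")
  p <- p_default; p$kact_fb <- -1
  expect_error(register_reduced_model(p), "kact_fb")
})

test_that("platelet-bound rate functions vanish without platelets; feedback off makes E2b production linear in E1b", {
  reg <- register_reduced_model(p_default)
  y <- wellmixed_init(p_default, E1 = 5)
  y$S2b <- 0; y$E1b <- 0; y$E2b <- 0
  r <- network_rates(reg, y, P_bound = 0)
  expect_equal(r$E1b, 0)     # no binding sites
  expect_equal(r$S2b, 0)
  expect_equal(r$E2b, 0)
  ## feedback rate zero: dE2b/dt at fixed S2b doubles when E1b doubles
  p0 <- p_default; p0$kact_fb <- 0
  reg0 <- register_reduced_model(p0)
  y1 <- y; y1$E1b <- 2; y1$S2b <- 7
  y2 <- y; y2$E1b <- 4; y2$S2b <- 7
  prod <- function(yy) {
    r <- network_rates(reg0, yy, P_bound = 0.01)
    r$E2b + p0$koff_e2 * yy$E2b   # activation part only
  }
  expect_equal(prod(y2), 2 * prod(y1))
})

test_that("RK4 on dC/dt = -lambda C reproduces the degree-4 Taylor polynomial and 4th-order convergence", {
  lam <- 1.7
  d <- function(f) list(C = -lam * f$C)
  h <- 0.3
  one <- rk4_react(list(C = 1), d, h, 1)$C
  z <- -lam * h
  expect_equal(one, 1 + z + z^2 / 2 + z^3 / 6 + z^4 / 24, tolerance = 1e-15)
  ## global error over T halves ~16x with h
  Tend <- 2
  err <- function(h) abs(rk4_react(list(C = 1), d, h, round(Tend / h))$C -
                           exp(-lam * Tend))
  r1 <- err(0.1) / err(0.05)
  expect_gt(r1, 12); expect_lt(r1, 20)
  ## zero rates leave the state bitwise unchanged
  y0 <- list(A = matrix(runif(4), 2, 2))
  y1 <- rk4_react(y0, function(f) list(A = 0 * f$A), 0.1, 3)
  expect_identical(y0$A, y1$A)
  expect_error(rk4_react(list(C = 1), function(f) list(C = NaN), 0.1, 1),
               "non-finite")
})

test_that("stoichiometric invariants hold along RK4 trajectories from random states", {
  reg <- register_reduced_model(p_default)
  d <- registry_derivative(reg, P_bound = 0.02)
  set.seed(31)
  for (rep in 1:4) {
    y <- list(S1 = runif(1, 0, 200), E1 = runif(1, 0, 5), S2 = runif(1, 0, 1500),
              E2 = runif(1, 0, 10), I1 = runif(1, 0, 60), I2 = runif(1, 0, 2500),
              E1I1 = runif(1, 0, 5), E2I2 = runif(1, 0, 10),
              E1b = runif(1, 0, 10), S2b = runif(1, 0, 30), E2b = runif(1, 0, 20))
    inv <- function(y) c(y$E1 + y$E1b + y$E1I1,
                         y$S2 + y$S2b + y$E2b + y$E2 + y$E2I2,
                         y$I1 + y$E1I1, y$I2 + y$E2I2)
    i0 <- inv(y)
    y2 <- rk4_react(y, d, 0.01, 200)
    expect_equal(inv(y2) / i0, rep(1, 4), tolerance = 1e-8)
  }
})

test_that("subendothelial surface reaction converts S1 to E1 one-to-one", {
  p <- p_default
  r <- se_surface_reaction(100, 0, p)
  expect_equal(r$S1_flux, 0); expect_equal(r$E1_flux, 0)
  r <- se_surface_reaction(c(50, 100), c(10, 10), p)
  expect_equal(r$E1_flux, -r$S1_flux)
  ## first-order in E0; Michaelis in S1
  r1 <- se_surface_reaction(5, 10, p); r2 <- se_surface_reaction(5, 20, p)
  expect_equal(r2$E1_flux, 2 * r1$E1_flux)
  expect_equal(r1$E1_flux, p$kcat0 * 10 * 5 / (p$KM0 + 5))
  expect_error(se_surface_reaction(5, -1, p), "non-negative")
})

test_that("wall conversion conserves S1 + E1 in a closed box", {
  cc <- tiny_channel_case()
  mesh <- cc$mesh
  p <- cc$config$params
  st <- new_simulation_state(mesh, cc$config)
  ## reaction stage only (no transport): total S1+E1+E1b+E1I1 is invariant
  fields0 <- c(st$chem, list(P_mu = st$plt$P_mu, P_ma = st$plt$P_ma,
                             P_ba = st$plt$P_ba, P_sea = st$plt$P_sea))
  tot0 <- sum((fields0$S1 + fields0$E1 + fields0$E1b + fields0$E1I1) *
                mesh$cell_volumes)
  for (k in 1:200) st <- fractional_step(st, transport = FALSE)
  tot <- sum((st$chem$S1 + st$chem$E1 + st$chem$E1b + st$chem$E1I1) *
               mesh$cell_volumes)
  expect_equal(tot / tot0, 1, tolerance = 1e-8)
  ## and E1 was actually produced at the wall
  expect_gt(max(st$chem$E1), 0)
  inj <- st$injury_faces
  expect_gt(st$chem$E1[inj$i[1], inj$j[1]], max(st$chem$E1) / 10)
})

test_that("inhibitor extension follows the two-step recipe and its closed forms", {
  reg <- register_reduced_model(p_default)
  ext <- add_inhibitor_extension(reg, k_I = 0.05)
  expect_equal(species_counts(ext)$coagulation, 14L)
  expect_error(add_inhibitor_extension(ext, 0.05), "collision")
  ## k_I = 0: dynamics identical to the base registry
  ext0 <- add_inhibitor_extension(reg, k_I = 0)
  y <- wellmixed_init(p_default, E1 = 2); y$I <- 50; y$E2_inh <- 0
  d_base <- registry_derivative(reg, 0.02)
  d_ext0 <- registry_derivative(ext0, 0.02)
  yb <- rk4_react(y[names(y) != "I" & names(y) != "E2_inh"], d_base, 0.01, 100)
  ye <- rk4_react(y, d_ext0, 0.01, 100)
  for (nm in names(yb)) expect_equal(ye[[nm]], yb[[nm]], info = nm)
  ## with E2 held fixed, I decays exponentially at rate k_I * E2
  kI <- 0.05; E2fix <- 8
  d_hold <- function(f) list(I = -kI * f$I * E2fix)
  yi <- rk4_react(list(I = 50), d_hold, 0.01, 500)
  expect_equal(yi$I, 50 * exp(-kI * E2fix * 5), tolerance = 1e-8)
  ## I + E2_inh is a conserved pair under the full extension dynamics
  d_ext <- registry_derivative(ext, 0.02)
  y2 <- rk4_react(y, d_ext, 0.01, 300)
  expect_equal(y2$I + y2$E2_inh, y$I + y$E2_inh, tolerance = 1e-8 * y$I)
  expect_gt(y2$E2_inh, 0)
})

test_that("thrombin curve diagnostics distinguish burst from graded generation", {
  reg <- register_reduced_model(p_default)
  run0 <- function(p, T = 400, nt = 400) {
    reg <- register_reduced_model(p)
    d <- registry_derivative(reg, P_bound = 0.01)
    y <- wellmixed_init(p)
    out <- matrix(0, nt + 1, 2)
    for (k in seq_len(nt)) {
      y <- rk4_react(y, d, 0.01, round(T / nt / 0.01))
      out[k + 1, ] <- c(k * T / nt, y$E2 + y$E2b)
    }
    out
  }
  o1 <- run0(p_default)
  d1 <- thrombin_burst_diagnostics(o1[, 1], o1[, 2])
  expect_true(d1$sigmoidal)
  expect_gt(d1$plateau, 1)
  ## no initiation: zero thrombin for all time
  pz <- p_default
  yz <- wellmixed_init(pz, E1 = 0)
  dz <- registry_derivative(register_reduced_model(pz), 0.01)
  yz2 <- rk4_react(yz, dz, 0.01, 500)
  expect_equal(yz2$E2 + yz2$E2b, 0)
  dflat <- thrombin_burst_diagnostics(c(0, 1, 2), c(0, 0, 0))
  expect_false(dflat$sigmoidal)
  expect_equal(dflat$plateau, 0)
})
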