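# Verification of the Navier-Stokes-Brinkman solver against closed-form
# channel solutions and its discrete conservation contracts.

## march the fluid to steady state on a wall-bounded channel driven by a
## kinematic body force gx, with zero-gradient ends (fully developed flow)
steady_channel <- function(ny, alpha_val = 0, gx = 1e4, nu = 1e5,
                           nsteps = 60, dt = 0.05, H = 30) {
  nx <- 4
  mesh <- rect_mesh(nx, ny, Lx = 10, Ly = H,
                    names = c(west = "outlet", east = "outlet", north = "walls"))
  ## both ends outflow-type (zero-gradient): 1-D fully developed channel
  fbc <- build_fluid_bc(mesh)
  st <- init_fluid_state(mesh, nu)
  alpha <- matrix(alpha_val, nx, ny)
  cache <- new_fluid_cache()
  for (k in seq_len(nsteps))
    st <- advance_fluid(st, alpha, dt, mesh, fbc, cache,
                        body_force = c(gx, 0))
  list(mesh = mesh, state = st)
}

test_that("zero forcing and zero initial velocity stay exactly at rest", {
  mesh <- rect_mesh(6, 4)
  fbc <- build_fluid_bc(mesh, inflow = list(inlet = function(y) 0))
  st <- init_fluid_state(mesh, 1e5)
  st <- advance_fluid(st, matrix(0, 6, 4), 0.01, mesh, fbc)
  expect_true(all(st$u == 0))
  expect_true(all(st$v == 0))
})

test_that("pressure-driven channel converges to the Poiseuille profile within 1% on 32 cells", {
  gx <- 1e4; nu <- 1e5; H <- 30
  r <- steady_channel(32, gx = gx, nu = nu, H = H)
  u <- r$state$u[3, ]                       # mid-channel column
  y <- r$mesh$yc
  exact <- gx / (2 * nu) * y * (H - y)      # kinematic form of G*y*(H-y)/(2*mu)
  expect_lt(max(abs(u - exact)) / max(exact), 0.01)
  expect_lt(r$state$max_div * H / max(exact), 1e-8)
})

test_that("Poiseuille error converges at second order under grid refinement", {
  err <- function(ny) {
    gx <- 1e4; nu <- 1e5; H <- 30
    r <- steady_channel(ny, gx = gx, nu = nu, H = H)
    y <- r$mesh$yc
    max(abs(r$state$u[3, ] - gx / (2 * nu) * y * (H - y)))
  }
  e8 <- err(8); e16 <- err(16); e32 <- err(32)
  expect_gt(log2(e8 / e16), 1.9)
  expect_gt(log2(e16 / e32), 1.9)
})

test_that("a uniform inlet develops into a parabolic profile downstream", {
  ## at Re << 1 the entrance length is tiny, so the outlet profile is fully
  ## developed: u_max = 1.5 * u_mean
  mesh <- rect_mesh(24, 16, Lx = 360, Ly = 60)
  U <- 500
  fbc <- build_fluid_bc(mesh, inflow = list(inlet = function(y) U))
  st <- init_fluid_state(mesh, 1.2e6)
  cache <- new_fluid_cache()
  alpha <- matrix(0, 24, 16)
  for (k in 1:300) st <- advance_fluid(st, alpha, 0.01, mesh, fbc, cache)
  prof <- st$u[22, ]                      # x/H = 5.25: fully developed
  expect_equal(max(prof), 1.5 * U, tolerance = 0.02)
  y <- mesh$yc
  expect_lt(max(abs(prof - 6 * U * y * (60 - y) / 60^2)) / (1.5 * U), 0.02)
  ## global mass balance: inflow equals outflow
  qin <- sum(st$u[1, ]) * mesh$dy; qout <- sum(st$u[25, ]) * mesh$dy
  expect_equal(qout / qin, 1, tolerance = 1e-10)
})

test_that("the Darcy limit is recovered in a high-resistance channel within 5%", {
  ## alpha*H^2 >> 1: mid-channel velocity -> gx / (nu * alpha)
  gx <- 1e4; nu <- 1e5; alpha <- 0.4; H <- 30
  r <- steady_channel(16, alpha_val = alpha, gx = gx, nu = nu, H = H,
                      nsteps = 120)
  u_mid <- r$state$u[3, 8]
  expect_equal(u_mid, gx / (nu * alpha), tolerance = 0.05)
  ## full Brinkman profile: u(y) = u_D * (1 - cosh(k(y-H/2))/cosh(kH/2));
  ## compared over the core, away from the thin (~1/sqrt(alpha)) wall layer
  k <- sqrt(alpha)
  core <- r$mesh$yc > 5 & r$mesh$yc < H - 5
  exact <- gx / (nu * alpha) *
    (1 - cosh(k * (r$mesh$yc - H / 2)) / cosh(k * H / 2))
  expect_lt(max(abs(r$state$u[3, core] - exact[core])) / max(exact), 0.05)
})

test_that("Carman-Kozeny relation matches its printed closed form", {
  expect_equal(carman_kozeny_alpha(0), 0)
  expect_equal(carman_kozeny_alpha(0.5), 0.6 * 0.25 / (1 - 0.3)^3)
  expect_equal(carman_kozeny_alpha(0.5) / 0.4373, 1, tolerance = 1e-3)
  expect_equal(carman_kozeny_alpha(1), 0.6 / 0.4^3)   # 9.375 at the packing limit
  expect_equal(carman_kozeny_alpha(1), 9.375)
  expect_equal(carman_kozeny_alpha(0.3, C_CK = 2), 2 * carman_kozeny_alpha(0.3))
  expect_error(carman_kozeny_alpha(1.5), "theta_B")
  expect_error(carman_kozeny_alpha(-0.2), "theta_B")
  ## strictly increasing on [0, 1)
  th <- seq(0, 0.99, by = 0.01)
  expect_true(all(diff(carman_kozeny_alpha(th)) > 0))
})

test_that("PISO corrector: divergence-free input is left unchanged and any input is projected", {
  mesh <- rect_mesh(10, 8, Lx = 50, Ly = 40)
  fbc <- build_fluid_bc(mesh, inflow = list(inlet = function(y) 100))
  st <- init_fluid_state(mesh, 1e5)
  alpha <- matrix(0, 10, 8)
  cache <- new_fluid_cache()
  ## a divergence-free uniform field
  prov <- set_velocity_boundaries(matrix(100, 11, 8), matrix(0, 10, 9), fbc)
  st2 <- piso_corrector(st, prov, 2, alpha, 0.01, mesh, fbc, cache)
  expect_lt(max(abs(st2$u - prov$u)), 1e-10 * 100)
  ## a random provisional velocity is projected to the solver tolerance
  set.seed(3)
  prov <- set_velocity_boundaries(matrix(rnorm(88, sd = 50), 11, 8),
                                  matrix(rnorm(90, sd = 50), 10, 9), fbc)
  st3 <- piso_corrector(st, prov, 2, alpha, 0.01, mesh, fbc, cache)
  expect_lt(st3$max_div * 40 / 100, 1e-8)
})

test_that("kinetic energy decays without forcing and resistance reduces throughflow", {
  ## free decay in a closed box
  mesh <- box_mesh(8, 8, Lx = 40, Ly = 40)
  fbc <- build_fluid_bc(mesh)
  st <- init_fluid_state(mesh, 1e4)
  set.seed(5)
  prov <- set_velocity_boundaries(matrix(rnorm(72, sd = 10), 9, 8),
                                  matrix(rnorm(72, sd = 10), 8, 9), fbc)
  cache <- new_fluid_cache()
  st <- piso_corrector(st, prov, 2, matrix(0, 8, 8), 0.01, mesh, fbc, cache)
  ke <- function(s) sum(s$u^2) + sum(s$v^2)
  k0 <- ke(st)
  for (i in 1:10) {
    st <- advance_fluid(st, matrix(0, 8, 8), 0.01, mesh, fbc, cache)
    expect_lte(ke(st), k0 * (1 + 1e-12))
    k0 <- ke(st)
  }
  ## a resistive block in the lower half of a channel diverts flow upward
  mesh2 <- rect_mesh(16, 12, Lx = 80, Ly = 60)
  fbc2 <- build_fluid_bc(mesh2, inflow = list(inlet = function(y) 200))
  alpha2 <- matrix(0, 16, 12); alpha2[6:11, 1:6] <- 0.5
  st2 <- init_fluid_state(mesh2, 1e5)
  cache2 <- new_fluid_cache()
  for (i in 1:40) st2 <- advance_fluid(st2, alpha2, 0.02, mesh2, fbc2, cache2)
  q_low <- sum(st2$u[9, 1:6]); q_high <- sum(st2$u[9, 7:12])
  expect_lt(q_low, 0.2 * q_high)
  qin <- sum(st2$u[1, ]); qout <- sum(st2$u[17, ])
  expect_equal(qout / qin, 1, tolerance = 1e-10)
})
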