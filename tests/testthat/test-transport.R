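test_that("face interpolation schemes follow their definitions on a two-cell stencil", {
  mesh <- rect_mesh(2, 1, Lx = 2, Ly = 1)
  ## operators need ny >= 2; use a 2 x 2 grid with identical rows instead
  mesh <- rect_mesh(2, 2, Lx = 2, Ly = 2)
  C <- matrix(c(0.2, 0.8, 0.2, 0.8), 2, 2)
  fpos <- uniform_flux(mesh, u = 1)
  f <- interpolate_to_faces(C, "downwind", fpos, mesh)
  expect_equal(f$x[2, ], c(0.8, 0.8))
  f <- interpolate_to_faces(C, "upwind", fpos, mesh)
  expect_equal(f$x[2, ], c(0.2, 0.2))
  f <- interpolate_to_faces(C, "localMax", NULL, mesh)
  expect_equal(f$x[2, ], c(0.8, 0.8))
  ## larger value upstream: downwind and localMax differ exactly then
  C2 <- matrix(c(0.8, 0.2, 0.8, 0.2), 2, 2)
  f <- interpolate_to_faces(C2, "downwind", fpos, mesh)
  expect_equal(f$x[2, ], c(0.2, 0.2))
  f <- interpolate_to_faces(C2, "localMax", NULL, mesh)
  expect_equal(f$x[2, ], c(0.8, 0.8))
  ## zero-flux tie-break falls back to linear
  f <- interpolate_to_faces(C2, "downwind", zero_flux(mesh), mesh)
  expect_equal(f$x[2, ], c(0.5, 0.5))
  expect_error(interpolate_to_faces(C, "limitedLinear", NULL, mesh), "scheme")
  expect_error(interpolate_to_faces(C, "upwind", NULL, mesh), "flux")
})

test_that("every scheme preserves a uniform field and localMax dominates linear", {
  mesh <- rect_mesh(8, 6)
  flux <- uniform_flux(mesh, u = 2, v = -1)
  Cu <- matrix(0.37, 8, 6)
  for (s in c("linear", "upwind", "downwind", "localMax")) {
    f <- interpolate_to_faces(Cu, s, flux, mesh)
    expect_true(all(abs(f$x - 0.37) < 1e-15), info = s)
    expect_true(all(abs(f$y - 0.37) < 1e-15), info = s)
  }
  set.seed(42)
  for (rep in 1:5) {
    C <- matrix(runif(48), 8, 6)
    fmax <- interpolate_to_faces(C, "localMax", NULL, mesh)
    flin <- interpolate_to_faces(C, "linear", NULL, mesh)
    expect_true(all(fmax$x >= flin$x - 1e-15))
    expect_true(all(fmax$y >= flin$y - 1e-15))
  }
})

test_that("interpolation error orders on a sine profile: linear 2nd, upwind 1st", {
  err <- function(n, scheme) {
    mesh <- rect_mesh(n, 3, Lx = 1, Ly = 3)
    C <- matrix(sin(2 * pi * mesh$xc), n, 3)
    flux <- uniform_flux(mesh, u = 1)
    f <- interpolate_to_faces(C, scheme, flux, mesh)
    xf <- mesh$x_faces[2:n]
    max(abs(f$x[2:n, 1] - sin(2 * pi * xf)))
  }
  ord <- function(scheme) log2(err(16, scheme) / err(32, scheme))
  expect_gt(ord("linear"), 1.9)
  o <- ord("upwind")
  expect_gt(o, 0.8); expect_lt(o, 1.3)
})

test_that("divergence obeys the global budget identity", {
  mesh <- rect_mesh(6, 5)
  ## uniform flux: zero divergence everywhere
  d <- divergence(uniform_flux(mesh, u = 3, v = 2), mesh)
  expect_true(all(abs(d) < 1e-14))
  ## random flux: sum(div * V) telescopes to the net boundary flux
  set.seed(7)
  flux <- list(x = matrix(rnorm(7 * 5), 7, 5), y = matrix(rnorm(6 * 6), 6, 6))
  d <- divergence(flux, mesh)
  net_bnd <- sum(flux$x[7, ]) - sum(flux$x[1, ]) + sum(flux$y[, 6]) - sum(flux$y[, 1])
  expect_equal(sum(d * mesh$cell_volumes), net_bnd, tolerance = 1e-12)
})

test_that("transport step: identity with no flux and no diffusion; conservative diffusion", {
  mesh <- box_mesh(8, 6)
  set.seed(1)
  C <- matrix(runif(48), 8, 6)
  bc <- bc_all(mesh)
  r <- advance_transport(C, zero_flux(mesh), D = 0, dt = 0.1, mesh, bc)
  expect_equal(r$values, C, tolerance = 1e-15)
  ## diffusion in a closed box conserves mass to 1e-12 and spreads the field
  cache <- new_transport_cache()
  v0 <- stats::var(as.numeric(C))
  tot0 <- sum(C * mesh$cell_volumes)
  for (k in 1:20) {
    r <- advance_transport(C, zero_flux(mesh), D = 5, dt = 0.05, mesh, bc,
                           cache = cache)
    expect_lte(stats::var(as.numeric(r$values)), v0 + 1e-15)
    v0 <- stats::var(as.numeric(r$values))
    C <- r$values
  }
  expect_equal(sum(C * mesh$cell_volumes) / tot0, 1, tolerance = 1e-12)
})

test_that("upwind advection of a top-hat matches an independent 1-D reference", {
  nx <- 40
  mesh <- rect_mesh(nx, 3, Lx = 40, Ly = 3)
  u <- 2; dt <- 0.3; nstep <- 25    # Courant 0.6
  C <- matrix(as.numeric(mesh$xc > 8 & mesh$xc < 16), nx, 3)
  ref <- C[, 1]
  bc <- bc_all(mesh); bc$inlet <- list(kind = "fixed_value", value = 0)
  flux <- uniform_flux(mesh, u = u)
  cache <- new_transport_cache()
  x0 <- sum(mesh$xc * C[, 1]) / sum(C[, 1])
  for (k in seq_len(nstep)) {
    r <- advance_transport(C, flux, D = 0, dt = dt, mesh, bc, cache = cache)
    C <- r$values
    ## independent 1-D explicit upwind update
    ref <- ref - u * dt / mesh$dx * (ref - c(0, ref[-nx]))
  }
  expect_equal(C[, 2], ref, tolerance = 1e-12)
  x1 <- sum(mesh$xc * C[, 1]) / sum(C[, 1])
  expect_equal(x1 - x0, u * dt * nstep, tolerance = 0.15 * u * dt * nstep)
})

test_that("advective CFL violations are reported per the configured policy", {
  mesh <- rect_mesh(8, 3)
  C <- matrix(1, 8, 3)
  bc <- bc_all(mesh)
  fast <- uniform_flux(mesh, u = 20)   # Courant 2 at dt = 0.1
  expect_warning(advance_transport(C, fast, 0, 0.1, mesh, bc), "Courant")
  expect_error(advance_transport(C, fast, 0, 0.1, mesh, bc, cfl = "strict"),
               "Courant")
  expect_error(
    advance_transport(C, zero_flux(mesh), 0, 0.1, mesh, bc,
                      hindrance = list(adv = list(x = matrix(2, 9, 3),
                                                  y = matrix(1, 8, 4)),
                                       diff = list(x = matrix(1, 9, 3),
                                                   y = matrix(1, 8, 4)))),
    "hindrance")
})

test_that("fixed-value inflow budget closes exactly against the returned boundary terms", {
  mesh <- rect_mesh(10, 4, Lx = 10, Ly = 4)
  bc <- bc_all(mesh)
  bc$inlet <- list(kind = "fixed_value", value = 2)
  C <- matrix(0, 10, 4)
  flux <- uniform_flux(mesh, u = 1)
  cache <- new_transport_cache()
  tot <- sum(C * mesh$cell_volumes)
  influx <- 0
  for (k in 1:30) {
    r <- advance_transport(C, flux, D = 3, dt = 0.2, mesh, bc, cache = cache)
    influx <- influx + (r$bnd_adv_in + r$bnd_diff_in) * 0.2
    C <- r$values
  }
  expect_equal(sum(C * mesh$cell_volumes) - tot, influx, tolerance = 1e-10)
})

test_that("reactive Robin wall flux: zero rate is a zero-gradient wall; uptake scales with patch area", {
  mesh <- box_mesh(8, 4, injury_south = TRUE)
  C <- matrix(5, 8, 4)
  r0 <- apply_reactive_robin(C, mesh, function(cw) 0 * cw)
  expect_true(all(r0$cell_source == 0))
  ## constant-field linear uptake: total face flux is -k * C * A_patch
  k <- 0.3
  r1 <- apply_reactive_robin(C, mesh, function(cw) -k * cw)
  A <- sum(patch_face_segments(mesh, "injuryWalls")$length)
  expect_equal(sum(r1$faces$flux), -k * 5 * A, tolerance = 1e-12)
  ## doubling the patch length doubles the uptake
  mesh2 <- box_mesh(16, 4, Lx = 16, injury_south = TRUE)
  r2 <- apply_reactive_robin(matrix(5, 16, 4), mesh2, function(cw) -k * cw)
  expect_equal(sum(r2$faces$flux), 2 * sum(r1$faces$flux), tolerance = 1e-12)
  expect_error(apply_reactive_robin(C, mesh, function(cw) 0, patch = "walls"),
               "injuryWalls")
})

test_that("closed-box linear wall uptake follows the well-mixed decay law", {
  mesh <- box_mesh(6, 4, Lx = 6, Ly = 4, injury_south = TRUE)
  bc <- bc_all(mesh)
  k <- 0.05
  C <- matrix(1, 6, 4)
  cache <- new_transport_cache()
  dt <- 0.02; Tend <- 4
  for (s in seq_len(Tend / dt)) {
    rb <- apply_reactive_robin(C, mesh, function(cw) -k * cw)
    r <- advance_transport(C, zero_flux(mesh), D = 100, dt = dt, mesh, bc,
                           cache = cache, robin_source = rb$cell_source)
    C <- r$values
  }
  ## fast diffusion keeps the box well mixed: C ~ exp(-k*A/V * t)
  A <- sum(patch_face_segments(mesh, "injuryWalls")$length)
  V <- sum(mesh$cell_volumes)
  expect_equal(mean(C), exp(-k * A / V * Tend), tolerance = 0.01)
})
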