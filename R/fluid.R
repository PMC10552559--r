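#' Navier-Stokes-Brinkman fluid solver
#'
#' Incompressible flow of blood plasma with a Darcy friction term
#' `-nu * alpha(thetaB) * u` representing the resistance of the growing
#' platelet mass.  Velocity and pressure live on a staggered (MAC)
#' arrangement: x-velocity on vertical faces, y-velocity on horizontal faces,
#' kinematic pressure at cell centres.  Each time step performs one momentum
#' predictor solve (implicit diffusion, implicit Darcy term using the
#' bound-platelet fraction from the previous step, explicit advection, lagged
#' pressure gradient) followed by PISO-style pressure/velocity corrections in
#' which the corrective flux is damped by the Darcy diagonal, so
#' high-resistance regions receive proportionally less correction.
#'
#' Internal units: um, s; pressure is kinematic (um^2/s^2).
#'
#' @name fluid_brinkman
NULL

#' Carman-Kozeny inverse permeability
#'
#' `alpha(thetaB) = C_CK * 0.6 * thetaB^2 / (1 - 0.6 * thetaB)^3`, the
#' inverse permeability of a platelet mass with bound fraction `thetaB`.
#' The default constant 10^6 mm^-2 equals 1 um^-2 in internal units.
#'
#' @param theta_B bound platelet fraction, per cell, in \[0, 1\]
#' @param C_CK Carman-Kozeny constant (um^-2; default 1, i.e. 10^6 mm^-2)
#' @return inverse permeability (um^-2), same shape as `theta_B`
#' @export
carman_kozeny_alpha <- function(theta_B, C_CK = 1) {
  bad <- which(theta_B < -1e-8 | theta_B > 1 + 1e-8)
  if (length(bad) > 0)
    stop("theta_B outside [0, 1] at cell(s) ", paste(utils::head(bad, 5), collapse = ", "),
         " (value ", format(theta_B[bad[1]]), "); upstream boundedness violated")
  theta_B <- pmin(pmax(theta_B, 0), 1)
  C_CK * 0.6 * theta_B^2 / (1 - 0.6 * theta_B)^3
}

#' Initialise a fluid state
#'
#' @param mesh a `clot_mesh`
#' @param nu kinematic viscosity (um^2/s)
#' @param rho density (used only to report dynamic pressure; the solver works
#'   in kinematic units)
#' @return class `clot_fluid_state` with staggered `u`, `v`, pressure `p`
#' @export
init_fluid_state <- function(mesh, nu, rho = 1) {
  st <- list(u = matrix(0, mesh$nx + 1, mesh$ny),
             v = matrix(0, mesh$nx, mesh$ny + 1),
             p = matrix(0, mesh$nx, mesh$ny),
             nu = nu, rho = rho, max_div = NA_real_)
  class(st) <- "clot_fluid_state"
  st
}

#' Build the fluid boundary plan from the mesh patch types
#'
#' Wall patches are no-slip, inflow patches prescribe the (positive into the
#' domain) normal velocity, and outflow patches are zero-gradient in velocity
#' with a fixed reference pressure at the face.
#'
#' @param mesh a `clot_mesh`
#' @param inflow named list mapping inflow patch names to either a function
#'   of the along-boundary coordinate or a vector of per-face normal
#'   velocities (um/s)
#' @return per-side boundary plan consumed by the fluid solver
#' @export
build_fluid_bc <- function(mesh, inflow = list()) {
  type_code <- c(wall = 0L, inflow = 1L, outflow = 2L)
  plan <- list(
    west  = list(type = integer(mesh$ny), un = numeric(mesh$ny)),
    east  = list(type = integer(mesh$ny), un = numeric(mesh$ny)),
    south = list(type = integer(mesh$nx), un = numeric(mesh$nx)),
    north = list(type = integer(mesh$nx), un = numeric(mesh$nx)))
  for (pname in names(mesh$patches)) {
    faces <- mesh$patches[[pname]]
    tt <- type_code[[attr(faces, "type_tag")]]
    vals <- inflow[[pname]]
    for (k in seq_len(nrow(faces))) {
      side <- faces$side[k]
      pos <- if (side %in% c("west", "east")) faces$j[k] else faces$i[k]
      plan[[side]]$type[pos] <- tt
      if (tt == 1L) {
        if (is.null(vals)) stop("inflow patch '", pname, "' has no inflow values")
        crd <- if (side %in% c("west", "east")) mesh$yc[faces$j[k]] else mesh$xc[faces$i[k]]
        plan[[side]]$un[pos] <- if (is.function(vals)) vals(crd) else vals[[k]]
      }
    }
  }
  plan
}

#' Fill boundary values of a staggered velocity pair from the boundary plan
#'
#' @param u,v staggered velocity component arrays
#' @param fbc boundary plan from [build_fluid_bc()]
#' @return list with the completed `u`, `v`
#' @export
set_velocity_boundaries <- function(u, v, fbc) {
  nxp <- nrow(u); nyp <- ncol(v)
  w <- fbc$west; e <- fbc$east; s <- fbc$south; n <- fbc$north
  u[1, ] <- 0;   u[1, w$type == 1L] <- w$un[w$type == 1L]
  u[1, w$type == 2L] <- u[2, w$type == 2L]
  u[nxp, ] <- 0; u[nxp, e$type == 1L] <- -e$un[e$type == 1L]
  u[nxp, e$type == 2L] <- u[nxp - 1, e$type == 2L]
  v[, 1] <- 0;   v[s$type == 1L, 1] <- s$un[s$type == 1L]
  v[s$type == 2L, 1] <- v[s$type == 2L, 2]
  v[, nyp] <- 0; v[n$type == 1L, nyp] <- -n$un[n$type == 1L]
  v[n$type == 2L, nyp] <- v[n$type == 2L, nyp - 1]
  list(u = u, v = v)
}

## explicit advection terms at interior u- and v-nodes (conservative central)
mac_advection <- function(u, v, fbc, dx, dy) {
  nxp <- nrow(u); ny <- ncol(u); nx <- nrow(v); nyp <- ncol(v)
  ## d(uu)/dx at interior u-nodes i=2..nx
  ucc <- ((u[seq_len(nx), , drop = FALSE] + u[2:nxp, , drop = FALSE]) / 2)^2
  duu <- (ucc[2:nx, , drop = FALSE] - ucc[seq_len(nx - 1), , drop = FALSE]) / dx

  ## corner (vertex) values for the cross terms, rows i=2..nx, cols k=1..ny+1
  tang_wall <- function(type, inner) ifelse(type == 2L, inner, 0)
  ucor <- matrix(0, nx - 1, ny + 1)
  ucor[, 2:ny] <- (u[2:nx, seq_len(ny - 1), drop = FALSE] +
                   u[2:nx, 2:ny, drop = FALSE]) / 2
  ucor[, 1] <- tang_wall(fbc$south$type[2:nx], u[2:nx, 1])
  ucor[, ny + 1] <- tang_wall(fbc$north$type[2:nx], u[2:nx, ny])
  vcor <- (v[seq_len(nx - 1), , drop = FALSE] + v[2:nx, , drop = FALSE]) / 2
  uv <- ucor * vcor
  duv <- (uv[, 2:(ny + 1), drop = FALSE] - uv[, seq_len(ny), drop = FALSE]) / dy
  adv_u <- duu + duv

  ## d(vv)/dy at interior v-nodes j=2..ny
  vcc <- ((v[, seq_len(ny), drop = FALSE] + v[, 2:nyp, drop = FALSE]) / 2)^2
  dvv <- (vcc[, 2:ny, drop = FALSE] - vcc[, seq_len(ny - 1), drop = FALSE]) / dy
  vcor2 <- matrix(0, nx + 1, ny - 1)
  vcor2[2:nx, ] <- (v[seq_len(nx - 1), 2:ny, drop = FALSE] +
                    v[2:nx, 2:ny, drop = FALSE]) / 2
  vcor2[1, ] <- tang_wall(fbc$west$type[2:ny], v[1, 2:ny])
  vcor2[nx + 1, ] <- tang_wall(fbc$east$type[2:ny], v[nx, 2:ny])
  ucor2 <- (u[, seq_len(ny - 1), drop = FALSE] + u[, 2:ny, drop = FALSE]) / 2
  uv2 <- ucor2 * vcor2
  dvu <- (uv2[2:(nx + 1), , drop = FALSE] - uv2[seq_len(nx), , drop = FALSE]) / dx
  adv_v <- dvv + dvu
  list(u = adv_u, v = adv_v)
}

#' Create a reusable fluid solver cache
#' @return an environment holding factorisations for the momentum and
#'   pressure equations
#' @export
new_fluid_cache <- function() new.env(parent = emptyenv())

#' Momentum predictor
#'
#' One implicit solve of the discretised momentum equation: backward-Euler
#' diffusion, implicit Darcy term `-nu * alpha * u` (with `alpha` from the
#' previous step's bound-platelet fraction), explicit conservative advection
#' and the lagged pressure gradient.
#'
#' @param state a `clot_fluid_state`
#' @param alpha per-cell inverse permeability (um^-2), `nx x ny`
#' @param dt time step (s)
#' @param mesh a `clot_mesh`
#' @param fbc fluid boundary plan from `build_fluid_bc()`
#' @param cache environment from [new_fluid_cache()]
#' @param body_force kinematic body force `c(gx, gy)` (um/s^2)
#' @param grad_p optional lagged pressure field to use (defaults to `state$p`)
#' @return list with provisional `u`, `v` (boundary values filled)
#' @export
momentum_predictor <- function(state, alpha, dt, mesh, fbc,
                               cache = NULL, body_force = c(0, 0),
                               grad_p = NULL) {
  nx <- mesh$nx; ny <- mesh$ny; dx <- mesh$dx; dy <- mesh$dy
  nu <- state$nu
  p <- if (is.null(grad_p)) state$p else grad_p
  if (is.null(cache)) cache <- new_fluid_cache()
  bv <- set_velocity_boundaries(state$u, state$v, fbc)
  u <- bv$u; v <- bv$v
  adv <- mac_advection(u, v, fbc, dx, dy)

  ax <- nu / dx^2; ay <- nu / dy^2
  wt <- fbc$west$type; et <- fbc$east$type
  stt <- fbc$south$type; ntt <- fbc$north$type
  wfix <- wt != 2L; efix <- et != 2L
  sfix <- stt != 2L; nfix <- ntt != 2L

  ## ---- u equation: unknowns at interior vertical faces (nx-1) x ny -------
  key_u <- list(dt = dt, nu = nu, alpha = alpha, bc = fbc)
  if (is.null(cache$su)) cache$su <- make_penta_solver(nx - 1, ny)
  if (!identical(cache$key_u, key_u)) {
    alpha_u <- (alpha[seq_len(nx - 1), , drop = FALSE] + alpha[2:nx, , drop = FALSE]) / 2
    aE <- matrix(ax, nx - 1, ny); aE[nx - 1, ] <- 0
    aN <- matrix(ay, nx - 1, ny); aN[, ny] <- 0
    lsum <- matrix(0, nx - 1, ny)
    lsum[seq_len(nx - 2), ] <- lsum[seq_len(nx - 2), ] + ax   # east link
    lsum[2:(nx - 1), ] <- lsum[2:(nx - 1), ] + ax             # west link
    lsum[, seq_len(ny - 1)] <- lsum[, seq_len(ny - 1)] + ay   # north
    lsum[, 2:ny] <- lsum[, 2:ny] + ay                         # south
    diagv <- 1 / dt + nu * alpha_u + lsum
    ## x-boundary neighbours (known boundary u values unless outflow)
    diagv[1, wfix] <- diagv[1, wfix] + ax
    diagv[nx - 1, efix] <- diagv[nx - 1, efix] + ax
    ## tangential wall/inflow boundaries: ghost reflection adds 2*ay
    st2 <- stt[2:nx]; nt2 <- ntt[2:nx]
    diagv[st2 != 2L, 1] <- diagv[st2 != 2L, 1] + 2 * ay
    diagv[nt2 != 2L, ny] <- diagv[nt2 != 2L, ny] + 2 * ay
    cache$su$set_coefficients(as.numeric(diagv), as.numeric(aE), as.numeric(aN))
    cache$key_u <- key_u
  }
  rhs <- u[2:nx, , drop = FALSE] / dt - adv$u + body_force[1] -
    (p[2:nx, , drop = FALSE] - p[seq_len(nx - 1), , drop = FALSE]) / dx
  rhs[1, wfix] <- rhs[1, wfix] + ax * u[1, wfix]
  rhs[nx - 1, efix] <- rhs[nx - 1, efix] + ax * u[nx + 1, efix]
  ustar <- u
  ustar[2:nx, ] <- matrix(cache$su$solve(as.numeric(rhs)), nx - 1, ny)

  ## ---- v equation: unknowns at interior horizontal faces nx x (ny-1) -----
  key_v <- list(dt = dt, nu = nu, alpha = alpha, bc = fbc)
  if (is.null(cache$sv)) cache$sv <- make_penta_solver(nx, ny - 1)
  if (!identical(cache$key_v, key_v)) {
    alpha_v <- (alpha[, seq_len(ny - 1), drop = FALSE] + alpha[, 2:ny, drop = FALSE]) / 2
    aEv <- matrix(ax, nx, ny - 1); aEv[nx, ] <- 0
    aNv <- matrix(ay, nx, ny - 1); aNv[, ny - 1] <- 0
    lsum <- matrix(0, nx, ny - 1)
    lsum[seq_len(nx - 1), ] <- lsum[seq_len(nx - 1), ] + ax
    lsum[2:nx, ] <- lsum[2:nx, ] + ax
    lsum[, seq_len(ny - 2)] <- lsum[, seq_len(ny - 2)] + ay
    lsum[, 2:(ny - 1)] <- lsum[, 2:(ny - 1)] + ay
    diagv <- 1 / dt + nu * alpha_v + lsum
    diagv[sfix, 1] <- diagv[sfix, 1] + ay
    diagv[nfix, ny - 1] <- diagv[nfix, ny - 1] + ay
    wt2 <- wt[2:ny]; et2 <- et[2:ny]
    diagv[1, wt2 != 2L] <- diagv[1, wt2 != 2L] + 2 * ax
    diagv[nx, et2 != 2L] <- diagv[nx, et2 != 2L] + 2 * ax
    cache$sv$set_coefficients(as.numeric(diagv), as.numeric(aEv), as.numeric(aNv))
    cache$key_v <- key_v
  }
  rhs <- v[, 2:ny, drop = FALSE] / dt - adv$v + body_force[2] -
    (p[, 2:ny, drop = FALSE] - p[, seq_len(ny - 1), drop = FALSE]) / dy
  rhs[sfix, 1] <- rhs[sfix, 1] + ay * v[sfix, 1]
  rhs[nfix, ny - 1] <- rhs[nfix, ny - 1] + ay * v[nfix, ny + 1]
  vstar <- v
  vstar[, 2:ny] <- matrix(cache$sv$solve(as.numeric(rhs)), nx, ny - 1)

  bv <- set_velocity_boundaries(ustar, vstar, fbc)
  list(u = bv$u, v = bv$v)
}

## divergence of the staggered velocity (1/s)
velocity_divergence <- function(u, v, mesh) {
  nx <- mesh$nx; ny <- mesh$ny
  (u[2:(nx + 1), , drop = FALSE] - u[seq_len(nx), , drop = FALSE]) / mesh$dx +
  (v[, 2:(ny + 1), drop = FALSE] - v[, seq_len(ny), drop = FALSE]) / mesh$dy
}

#' PISO pressure-velocity correction
#'
#' Repeatedly solves the variable-coefficient pressure-correction equation
#' whose face conductances are damped by the transient+Darcy diagonal
#' `a = 1/dt + nu * alpha_face`, then corrects face velocities and pressure,
#' driving the discrete divergence to the linear-solver level.
#'
#' @param state a `clot_fluid_state` (supplies `p` and `nu`)
#' @param provisional list with provisional `u`, `v` from
#'   [momentum_predictor()]
#' @param n_correctors number of corrector sweeps (default 2)
#' @param alpha per-cell inverse permeability
#' @param dt time step (s)
#' @param mesh a `clot_mesh`
#' @param fbc fluid boundary plan
#' @param cache environment from [new_fluid_cache()]
#' @return updated `clot_fluid_state` with divergence-free `u`, `v`, updated
#'   `p` and `max_div`
#' @export
piso_corrector <- function(state, provisional, n_correctors = 2, alpha,
                           dt, mesh, fbc, cache = NULL) {
  stopifnot(n_correctors >= 1)
  nx <- mesh$nx; ny <- mesh$ny; dx <- mesh$dx; dy <- mesh$dy
  nu <- state$nu
  if (is.null(cache)) cache <- new_fluid_cache()
  u <- provisional$u; v <- provisional$v; p <- state$p

  out_e <- fbc$east$type == 2L; out_w <- fbc$west$type == 2L
  out_n <- fbc$north$type == 2L; out_s <- fbc$south$type == 2L
  closed <- !any(out_e) && !any(out_w) && !any(out_n) && !any(out_s)
  if (is.null(cache$sp)) cache$sp <- make_penta_solver(nx, ny)
  key_p <- list(dt = dt, nu = nu, alpha = alpha, bc = fbc)
  if (!identical(cache$key_p, key_p)) {
    a_u <- 1 / dt + nu * (alpha[seq_len(nx - 1), , drop = FALSE] +
                          alpha[2:nx, , drop = FALSE]) / 2        # interior u-faces
    a_v <- 1 / dt + nu * (alpha[, seq_len(ny - 1), drop = FALSE] +
                          alpha[, 2:ny, drop = FALSE]) / 2
    ## conductances between cell pairs across interior faces
    cE <- matrix(0, nx, ny); cN <- matrix(0, nx, ny)
    cE[seq_len(nx - 1), ] <- dy / (a_u * dx)
    cN[, seq_len(ny - 1)] <- dx / (a_v * dy)
    cW <- rbind(0, cE[seq_len(nx - 1), , drop = FALSE])
    cS <- cbind(0, cN[, seq_len(ny - 1), drop = FALSE])
    diagv <- cE + cW + cN + cS
    ## outflow faces: Dirichlet p' = 0 at the face (half-cell conductance)
    a_bnd <- 1 / dt + nu * alpha
    ce_b <- dy / (a_bnd[nx, ] * (dx / 2)); cw_b <- dy / (a_bnd[1, ] * (dx / 2))
    cn_b <- dx / (a_bnd[, ny] * (dy / 2)); cs_b <- dx / (a_bnd[, 1] * (dy / 2))
    diagv[nx, out_e] <- diagv[nx, out_e] + ce_b[out_e]
    diagv[1, out_w] <- diagv[1, out_w] + cw_b[out_w]
    diagv[out_n, ny] <- diagv[out_n, ny] + cn_b[out_n]
    diagv[out_s, 1] <- diagv[out_s, 1] + cs_b[out_s]
    if (closed) {
      ## all-Neumann problem: pin the reference cell (1,1) at p' = 0
      cE[1, 1] <- 0
      if (ny > 1) cN[1, 1] <- 0
      diagv[1, 1] <- 1
    }
    cache$sp$set_coefficients(as.numeric(diagv), as.numeric(cE), as.numeric(cN))
    cache$pc <- list(a_u = a_u, a_v = a_v, a_bnd = a_bnd)
    cache$key_p <- key_p
  }
  a_u <- cache$pc$a_u; a_v <- cache$pc$a_v; a_bnd <- cache$pc$a_bnd

  for (sweep in seq_len(n_correctors)) {
    div <- velocity_divergence(u, v, mesh)
    r <- -div * mesh$cell_volumes
    if (closed) r[1, 1] <- 0
    pc <- matrix(cache$sp$solve(as.numeric(r)), nx, ny)
    ## correct interior faces
    u[2:nx, ] <- u[2:nx, ] -
      (pc[2:nx, , drop = FALSE] - pc[seq_len(nx - 1), , drop = FALSE]) / (a_u * dx)
    v[, 2:ny] <- v[, 2:ny] -
      (pc[, 2:ny, drop = FALSE] - pc[, seq_len(ny - 1), drop = FALSE]) / (a_v * dy)
    ## correct outflow boundary faces (p' = 0 outside)
    u[nx + 1, out_e] <- u[nx + 1, out_e] + 2 * pc[nx, out_e] / (a_bnd[nx, out_e] * dx)
    u[1, out_w] <- u[1, out_w] - 2 * pc[1, out_w] / (a_bnd[1, out_w] * dx)
    v[out_n, ny + 1] <- v[out_n, ny + 1] + 2 * pc[out_n, ny] / (a_bnd[out_n, ny] * dy)
    v[out_s, 1] <- v[out_s, 1] - 2 * pc[out_s, 1] / (a_bnd[out_s, 1] * dy)
    p <- p + pc
  }
  state$u <- u; state$v <- v; state$p <- p
  state$max_div <- max(abs(velocity_divergence(u, v, mesh)))
  state
}

#' Advance the fluid by one time step
#'
#' Momentum predictor followed by the PISO corrector loop.
#'
#' @inheritParams momentum_predictor
#' @param n_correctors corrector sweeps (default 2)
#' @return updated `clot_fluid_state`
#' @export
advance_fluid <- function(state, alpha, dt, mesh, fbc, cache = NULL,
                          n_correctors = 2, body_force = c(0, 0)) {
  if (is.null(cache)) cache <- new_fluid_cache()
  prov <- momentum_predictor(state, alpha, dt, mesh, fbc, cache, body_force)
  piso_corrector(state, prov, n_correctors, alpha, dt, mesh, fbc, cache)
}
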