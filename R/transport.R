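#' Finite-volume transport operators
#'
#' Cell-centred advection-diffusion operators for scalar species: face
#' interpolation schemes (including the downwind and local-maximum schemes
#' used to bound platelet packing), a conservative transport step with
#' explicit upwind advection and implicit (backward-Euler) diffusion, boundary
#' conditions including reactive (Robin) injured-wall fluxes, and the discrete
#' divergence.
#'
#' Scalar fields are `nx x ny` matrices; face-indexed arrays are
#' `(nx+1) x ny` (x-faces) and `nx x (ny+1)` (y-faces).  Face fluxes are
#' volumetric (um^3/s with unit depth), signed positive towards increasing
#' i or j.
#'
#' @name fvm_transport
NULL

#' Face fluxes from a staggered velocity field
#'
#' @param u x-velocity on vertical faces, `(nx+1) x ny` (um/s)
#' @param v y-velocity on horizontal faces, `nx x (ny+1)` (um/s)
#' @param mesh a `clot_mesh`
#' @return list with components `x`, `y` of signed volumetric face fluxes
#' @export
face_flux_field <- function(u, v, mesh) {
  list(x = u * mesh$dy, y = v * mesh$dx)
}

#' Interpolate a cell field to interior and boundary faces
#'
#' Schemes: `linear` (distance-weighted average; arithmetic mean on the
#' uniform grids used here), `upwind`/`downwind` (value of the cell up- or
#' downstream of the face flux; faces with exactly zero flux fall back to
#' linear), and `localMax` (maximum of the two adjacent cell values).
#' Boundary faces take the adjacent cell value.
#'
#' @param field `nx x ny` matrix
#' @param scheme one of `"linear"`, `"upwind"`, `"downwind"`, `"localMax"`
#' @param flux face-flux list (required for upwind/downwind)
#' @param mesh a `clot_mesh`
#' @return list with `x` (`(nx+1) x ny`) and `y` (`nx x (ny+1)`) face values
#' @export
interpolate_to_faces <- function(field, scheme, flux = NULL, mesh) {
  if (!scheme %in% c("linear", "upwind", "downwind", "localMax"))
    stop("configuration error: unknown interpolation scheme '", scheme, "'")
  if (scheme %in% c("upwind", "downwind") && is.null(flux))
    stop(scheme, " interpolation requires a face flux")
  nx <- mesh$nx; ny <- mesh$ny
  fx <- matrix(0, nx + 1, ny); fy <- matrix(0, nx, ny + 1)
  L <- field[seq_len(nx - 1), , drop = FALSE]    # lower-i cell of interior x-face
  R <- field[2:nx, , drop = FALSE]
  B <- field[, seq_len(ny - 1), drop = FALSE]    # lower-j cell of interior y-face
  U <- field[, 2:ny, drop = FALSE]
  ## upwind/downwind via sign arithmetic: sign(f) = 0 gives the linear mean
  pick <- function(lo, hi, f) {
    switch(scheme,
      linear   = (lo + hi) / 2,
      localMax = pmax(lo, hi),
      upwind   = ((lo + hi) + sign(f) * (lo - hi)) / 2,
      downwind = ((lo + hi) - sign(f) * (lo - hi)) / 2)
  }
  fi <- if (!is.null(flux)) flux$x[2:nx, , drop = FALSE] else NULL
  fx[2:nx, ] <- pick(L, R, fi)
  fj <- if (!is.null(flux)) flux$y[, 2:ny, drop = FALSE] else NULL
  fy[, 2:ny] <- pick(B, U, fj)
  fx[1, ] <- field[1, ]; fx[nx + 1, ] <- field[nx, ]
  fy[, 1] <- field[, 1]; fy[, ny + 1] <- field[, ny]
  list(x = fx, y = fy)
}

#' Discrete divergence of a face-flux field
#'
#' Net signed face flux out of each cell divided by cell volume.
#'
#' @param flux face-flux list (`x`, `y`)
#' @param mesh a `clot_mesh`
#' @return `nx x ny` matrix (1/s)
#' @export
divergence <- function(flux, mesh) {
  nx <- mesh$nx; ny <- mesh$ny
  (flux$x[2:(nx + 1), , drop = FALSE] - flux$x[seq_len(nx), , drop = FALSE] +
   flux$y[, 2:(ny + 1), drop = FALSE] - flux$y[, seq_len(ny), drop = FALSE]) /
    mesh$cell_volumes
}

## Per-side boundary-condition plan derived from the per-patch spec.
## kinds: 0 zero_gradient, 1 fixed_value (also inflow_value), 3 reactive_robin
build_bc_plan <- function(mesh, bc) {
  plan <- list(
    west  = list(kind = integer(mesh$ny), value = numeric(mesh$ny)),
    east  = list(kind = integer(mesh$ny), value = numeric(mesh$ny)),
    south = list(kind = integer(mesh$nx), value = numeric(mesh$nx)),
    north = list(kind = integer(mesh$nx), value = numeric(mesh$nx)))
  for (pname in names(bc)) {
    spec <- bc[[pname]]
    faces <- mesh$patches[[pname]]
    if (is.null(faces)) stop("boundary condition for unknown patch '", pname, "'")
    kind <- switch(spec$kind,
      zero_gradient = 0L, fixed_value = 1L, inflow_value = 1L,
      reactive_robin = 3L,
      stop("unknown boundary condition kind '", spec$kind, "'"))
    if (kind == 3L && pname != "injuryWalls")
      stop("reactive_robin boundary conditions are only allowed on injuryWalls")
    for (k in seq_len(nrow(faces))) {
      side <- faces$side[k]
      pos <- if (side %in% c("west", "east")) faces$j[k] else faces$i[k]
      plan[[side]]$kind[pos] <- kind
      if (kind == 1L) plan[[side]]$value[pos] <- spec$value
    }
  }
  for (s in BOUNDARY_SIDES) plan[[s]]$fixed <- plan[[s]]$kind == 1L
  plan
}

#' Create a reusable transport solver cache
#'
#' Holds the boundary-condition plan, the sparsity pattern and the Cholesky
#' factorisation of the implicit diffusion operator; pass the same cache on
#' every step for a given species (or group of species sharing diffusivity
#' and hindrance).
#' @return an environment
#' @export
new_transport_cache <- function() new.env(parent = emptyenv())

#' Transport step for a block of species sharing one operator
#'
#' Advances several species that share the flux, diffusivity, hindrance and
#' boundary-condition *kinds* (boundary values may differ per species) in a
#' single implicit solve with multiple right-hand sides; this is the
#' performance path used by the solver loop for the fluid-phase proteins and
#' the mobile platelet pair.
#'
#' @inheritParams advance_transport
#' @param C_list named list of `nx x ny` field matrices
#' @param bc_list list of per-patch boundary specs, one per species
#' @param robin_sources optional list of per-species boundary reaction
#'   sources
#' @param diffusion `"implicit"` (backward Euler, default) or `"explicit"`
#'   (forward Euler; appropriate when the face coefficients change every
#'   step and `D * dt / dx^2` is small)
#' @return list with `values` (list of new fields), per-species
#'   `bnd_adv_in`, `bnd_diff_in` and the advective `courant` number
#' @export
advance_transport_block <- function(C_list, flux, D, dt, mesh, bc_list,
                                    hindrance = NULL, cache = NULL,
                                    scheme = "upwind", robin_sources = NULL,
                                    cfl = "warn", diffusion = "implicit") {
  stopifnot(dt > 0)
  nx <- mesh$nx; ny <- mesh$ny
  dx <- mesh$dx; dy <- mesh$dy
  V <- dx * dy
  ns <- length(C_list)
  if (is.null(cache)) cache <- new_transport_cache()
  if (!is.null(hindrance)) {
    rng <- range(hindrance$adv$x, hindrance$adv$y,
                 hindrance$diff$x, hindrance$diff$y)
    if (rng[1] < -1e-12 || rng[2] > 1 + 1e-12)
      stop("hindrance multipliers must lie in [0, 1]")
  }

  if (!identical(cache$bc_list, bc_list)) {
    plans <- lapply(bc_list, function(b) build_bc_plan(mesh, b))
    k0 <- lapply(plans[[1]], `[[`, "kind")
    for (p in plans)
      if (!identical(lapply(p, `[[`, "kind"), k0))
        stop("species in one transport block must share boundary-condition kinds")
    cache$plans <- plans
    cache$bc_list <- bc_list
    cache$sig <- NULL
  }
  plans <- cache$plans
  plan1 <- plans[[1]]

  co <- dt * (max(abs(flux$x)) / (dy * dx) + max(abs(flux$y)) / (dx * dy))
  if (co > 0.9 + 1e-12) {
    msg <- sprintf("advective Courant number %.3f exceeds 0.9", co)
    if (identical(cfl, "strict")) stop(msg)
    if (identical(cfl, "warn")) warning(msg)
  }

  Wa_x <- if (is.null(hindrance)) 1 else hindrance$adv$x
  Wa_y <- if (is.null(hindrance)) 1 else hindrance$adv$y

  ## boundary advective face values: inflowing fixed faces carry the bc value
  Fw <- flux$x[1, ]; Fe <- flux$x[nx + 1, ]
  Fs <- flux$y[, 1]; Fn <- flux$y[, ny + 1]
  in_w <- Fw > 0 & plan1$west$fixed;  in_e <- Fe < 0 & plan1$east$fixed
  in_s <- Fs > 0 & plan1$south$fixed; in_n <- Fn < 0 & plan1$north$fixed

  rhs <- matrix(0, nx * ny, ns)
  bnd_adv_in <- numeric(ns)
  for (s in seq_len(ns)) {
    C <- C_list[[s]]
    Cf <- interpolate_to_faces(C, scheme, flux, mesh)
    pl <- plans[[s]]
    Cf$x[1, in_w] <- pl$west$value[in_w]
    Cf$x[nx + 1, in_e] <- pl$east$value[in_e]
    Cf$y[in_s, 1] <- pl$south$value[in_s]
    Cf$y[in_n, ny + 1] <- pl$north$value[in_n]
    adv_x <- flux$x * Wa_x * Cf$x
    adv_y <- flux$y * Wa_y * Cf$y
    net_out <- adv_x[2:(nx + 1), , drop = FALSE] - adv_x[seq_len(nx), , drop = FALSE] +
               adv_y[, 2:(ny + 1), drop = FALSE] - adv_y[, seq_len(ny), drop = FALSE]
    bnd_adv_in[s] <- sum(adv_x[1, ]) - sum(adv_x[nx + 1, ]) +
                     sum(adv_y[, 1]) - sum(adv_y[, ny + 1])
    r <- (V / dt) * C - net_out
    if (!is.null(robin_sources) && !is.null(robin_sources[[s]]))
      r <- r + V * robin_sources[[s]]
    rhs[, s] <- r
  }

  bnd_diff_in <- numeric(ns)
  if (D > 0 && diffusion == "explicit") {
    ## forward-Euler diffusion (used where the hindered face coefficients
    ## change every step and the cell Fourier number D*dt/dx^2 is small)
    Wd_x <- if (is.null(hindrance)) 1 else hindrance$diff$x
    Wd_y <- if (is.null(hindrance)) 1 else hindrance$diff$y
    wx1 <- if (is.null(hindrance)) rep(1, ny) else Wd_x[1, ]
    wx2 <- if (is.null(hindrance)) rep(1, ny) else Wd_x[nx + 1, ]
    wy1 <- if (is.null(hindrance)) rep(1, nx) else Wd_y[, 1]
    wy2 <- if (is.null(hindrance)) rep(1, nx) else Wd_y[, ny + 1]
    out <- vector("list", ns)
    for (s in seq_len(ns)) {
      C <- C_list[[s]]
      pl <- plans[[s]]
      dfx <- matrix(0, nx + 1, ny); dfy <- matrix(0, nx, ny + 1)
      dfx[2:nx, ] <- -D * dy / dx *
        (C[2:nx, , drop = FALSE] - C[seq_len(nx - 1), , drop = FALSE])
      dfy[, 2:ny] <- -D * dx / dy *
        (C[, 2:ny, drop = FALSE] - C[, seq_len(ny - 1), drop = FALSE])
      if (!is.null(hindrance)) {
        dfx <- dfx * Wd_x; dfy <- dfy * Wd_y
      }
      f <- pl$west$fixed
      dfx[1, f] <- -2 * D * wx1[f] * dy / dx * (C[1, f] - pl$west$value[f])
      f <- pl$east$fixed
      dfx[nx + 1, f] <- -2 * D * wx2[f] * dy / dx * (pl$east$value[f] - C[nx, f])
      f <- pl$south$fixed
      dfy[f, 1] <- -2 * D * wy1[f] * dx / dy * (C[f, 1] - pl$south$value[f])
      f <- pl$north$fixed
      dfy[f, ny + 1] <- -2 * D * wy2[f] * dx / dy * (pl$north$value[f] - C[f, ny])
      net_diff_out <- dfx[2:(nx + 1), , drop = FALSE] - dfx[seq_len(nx), , drop = FALSE] +
                      dfy[, 2:(ny + 1), drop = FALSE] - dfy[, seq_len(ny), drop = FALSE]
      bnd_diff_in[s] <- sum(dfx[1, ]) - sum(dfx[nx + 1, ]) +
                        sum(dfy[, 1]) - sum(dfy[, ny + 1])
      out[[s]] <- matrix((rhs[, s] - net_diff_out) * dt / V, nx, ny)
    }
  } else if (D > 0) {
    Wd_x <- if (is.null(hindrance)) NULL else hindrance$diff$x
    Wd_y <- if (is.null(hindrance)) NULL else hindrance$diff$y
    sig <- list(D = D, dt = dt)
    rebuild <- is.null(cache$solver) || !identical(cache$sig, sig) ||
      !identical(cache$hind, Wd_x) || !identical(cache$hind_y, Wd_y)
    if (rebuild) {
      aE <- matrix(0, nx, ny); aN <- matrix(0, nx, ny)
      if (is.null(Wd_x)) {
        aE[seq_len(nx - 1), ] <- D * dy / dx
        aN[, seq_len(ny - 1)] <- D * dx / dy
      } else {
        aE[seq_len(nx - 1), ] <- D * Wd_x[2:nx, , drop = FALSE] * dy / dx
        aN[, seq_len(ny - 1)] <- D * Wd_y[, 2:ny, drop = FALSE] * dx / dy
      }
      aW <- rbind(0, aE[seq_len(nx - 1), , drop = FALSE])
      aS <- cbind(0, aN[, seq_len(ny - 1), drop = FALSE])
      ## fixed-value boundary faces contribute a half-cell conductance
      ab <- matrix(0, nx, ny)
      wdx1 <- if (is.null(Wd_x)) rep(1, ny) else Wd_x[1, ]
      wdx2 <- if (is.null(Wd_x)) rep(1, ny) else Wd_x[nx + 1, ]
      wdy1 <- if (is.null(Wd_y)) rep(1, nx) else Wd_y[, 1]
      wdy2 <- if (is.null(Wd_y)) rep(1, nx) else Wd_y[, ny + 1]
      f <- plan1$west$fixed;  ab[1, f]  <- ab[1, f]  + 2 * D * wdx1[f] * dy / dx
      f <- plan1$east$fixed;  ab[nx, f] <- ab[nx, f] + 2 * D * wdx2[f] * dy / dx
      f <- plan1$south$fixed; ab[f, 1]  <- ab[f, 1]  + 2 * D * wdy1[f] * dx / dy
      f <- plan1$north$fixed; ab[f, ny] <- ab[f, ny] + 2 * D * wdy2[f] * dx / dy
      diagv <- V / dt + aE + aW + aN + aS + ab
      if (is.null(cache$solver)) cache$solver <- make_penta_solver(nx, ny)
      cache$solver$set_coefficients(as.numeric(diagv), as.numeric(aE),
                                    as.numeric(aN))
      cache$ab <- ab
      ## per-species boundary-value source terms
      cache$bb <- lapply(plans, function(pl) {
        bb <- matrix(0, nx, ny)
        f <- pl$west$fixed;  bb[1, f]  <- bb[1, f]  + 2 * D * wdx1[f] * dy / dx * pl$west$value[f]
        f <- pl$east$fixed;  bb[nx, f] <- bb[nx, f] + 2 * D * wdx2[f] * dy / dx * pl$east$value[f]
        f <- pl$south$fixed; bb[f, 1]  <- bb[f, 1]  + 2 * D * wdy1[f] * dx / dy * pl$south$value[f]
        f <- pl$north$fixed; bb[f, ny] <- bb[f, ny] + 2 * D * wdy2[f] * dx / dy * pl$north$value[f]
        as.numeric(bb)
      })
      cache$sig <- sig
      cache$hind <- Wd_x
      cache$hind_y <- Wd_y
    }
    for (s in seq_len(ns)) rhs[, s] <- rhs[, s] + cache$bb[[s]]
    sol <- cache$solver$solve(rhs)
    if (ns == 1L) sol <- matrix(sol, ncol = 1)
    out <- vector("list", ns)
    abv <- as.numeric(cache$ab)
    for (s in seq_len(ns)) {
      out[[s]] <- matrix(sol[, s], nx, ny)
      bnd_diff_in[s] <- sum(cache$bb[[s]]) - sum(abv * sol[, s])
    }
  } else {
    out <- lapply(seq_len(ns), function(s) matrix(rhs[, s] * dt / V, nx, ny))
  }
  names(out) <- names(C_list)
  list(values = out, bnd_adv_in = bnd_adv_in, bnd_diff_in = bnd_diff_in,
       courant = co)
}

#' One conservative transport step (explicit upwind advection, implicit diffusion)
#'
#' Advances `dC/dt = -div(W v C - W D grad C)` by one step of size `dt`,
#' where `W` is an optional per-face hindrance multiplier (1 when absent; the
#' advective and diffusive faces may carry different multipliers).  Advection
#' is explicit with the requested face scheme; diffusion is backward Euler.
#' Interior fluxes telescope, so the step is discretely conservative; the
#' returned boundary-influx terms close the budget exactly.
#'
#' @param C `nx x ny` field matrix
#' @param flux face-flux list from [face_flux_field()]
#' @param D diffusivity (um^2/s)
#' @param dt time step (s)
#' @param mesh a `clot_mesh`
#' @param bc per-patch boundary spec: named list of
#'   `list(kind = "fixed_value"|"inflow_value"|"zero_gradient"|"reactive_robin",
#'   value = ...)`
#' @param hindrance `NULL`, or `list(adv = list(x, y), diff = list(x, y))` of
#'   per-face multipliers in \[0, 1\]
#' @param cache environment from [new_transport_cache()] (strongly
#'   recommended; rebuilt automatically when coefficients change)
#' @param scheme advective face scheme for the transported quantity
#'   (default `"upwind"`)
#' @param robin_source optional precomputed `nx x ny` boundary reaction
#'   source (nM/s), e.g. from [apply_reactive_robin()], added explicitly
#' @param cfl `"warn"` (default), `"strict"` (error) or `"silent"` for the
#'   advective Courant check at Co > 0.9
#' @return list with `values` (new field), `bnd_adv_in` and `bnd_diff_in`
#'   (net boundary influx, amount/s, evaluated consistently with the
#'   discretisation for budget accounting) and `courant`
#' @export
advance_transport <- function(C, flux, D, dt, mesh, bc,
                              hindrance = NULL, cache = NULL,
                              scheme = "upwind", robin_source = NULL,
                              cfl = "warn") {
  r <- advance_transport_block(list(C), flux, D, dt, mesh, list(bc),
                               hindrance = hindrance, cache = cache,
                               scheme = scheme,
                               robin_sources = list(robin_source),
                               cfl = cfl)
  list(values = r$values[[1]], bnd_adv_in = r$bnd_adv_in[1],
       bnd_diff_in = r$bnd_diff_in[1], courant = r$courant)
}

#' Reactive (Robin) boundary flux on the injured wall
#'
#' Evaluates a surface reaction rate on each `injuryWalls` face and converts
#' it into a volumetric source for the wall-adjacent cells.  The sign
#' convention is that a positive rate is a flux of the species *into* the
#' domain (production at the wall); consumption is negative.
#'
#' @param C `nx x ny` field matrix of the fluid-phase species (nM)
#' @param mesh a `clot_mesh`
#' @param surface_rate function of the wall-adjacent field values (vector,
#'   one per face) and `...`, returning the face flux density (nM um/s)
#' @param patch patch name; must be `injuryWalls`
#' @param ... further per-face arguments passed to `surface_rate`
#'   (e.g. wall-bound species values)
#' @return list with `faces` (data frame: face list plus `wall_value`,
#'   `flux_density` nM um/s, `flux` nM um^2/s) and `cell_source`
#'   (`nx x ny`, nM/s)
#' @export
apply_reactive_robin <- function(C, mesh, surface_rate,
                                 patch = "injuryWalls", ...) {
  if (patch != "injuryWalls")
    stop("reactive boundary conditions are only defined on injuryWalls")
  segs <- patch_face_segments(mesh, patch)
  wall_value <- C[cbind(segs$i, segs$j)]
  phi <- surface_rate(wall_value, ...)
  if (length(phi) == 1L) phi <- rep(phi, nrow(segs))
  stopifnot(length(phi) == nrow(segs))
  src <- matrix(0, mesh$nx, mesh$ny)
  contrib <- phi * segs$length / mesh$cell_volumes[cbind(segs$i, segs$j)]
  for (k in seq_len(nrow(segs)))
    src[segs$i[k], segs$j[k]] <- src[segs$i[k], segs$j[k]] + contrib[k]
  segs$wall_value <- wall_value
  segs$flux_density <- phi
  segs$flux <- phi * segs$length
  list(faces = segs, cell_source = src)
}
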