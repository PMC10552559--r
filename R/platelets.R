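#' Continuum platelet aggregation model
#'
#' Platelets are number densities (platelets/um^3) in four states: mobile
#' unactivated (`P_mu`), mobile activated (`P_ma`), bound activated (`P_ba`,
#' cohered to other bound platelets) and subendothelium-bound activated
#' (`P_sea`, adhered directly to the injured wall).  Mobile species are
#' transported with a hindered flux `W(thetaT) * (u P - D_P grad P)`; bound
#' species are immobile.  Source terms transfer platelets between states:
#' agonist-driven activation (Hill kinetics in ADP and fluid-phase thrombin),
#' adhesion to the subendothelium inside the wall-adhesion region, and
#' cohesion of activated platelets onto existing bound platelets modulated by
#' a binding-affinity function g of a chemical signal.
#'
#' @name platelet_model
NULL

#' Initialise a platelet state
#'
#' @param mesh a `clot_mesh`
#' @param P_max maximum packing number density (platelets/um^3)
#' @param D_P platelet diffusivity (um^2/s)
#' @param P_mu0 initial mobile-unactivated density (uniform or `nx x ny`)
#' @return class `clot_platelet_state` with the four density matrices
#' @export
init_platelet_state <- function(mesh, P_max, D_P, P_mu0 = 0) {
  z <- matrix(0, mesh$nx, mesh$ny)
  st <- list(P_mu = z + P_mu0, P_ma = z, P_ba = z, P_sea = z,
             P_max = P_max, D_P = D_P)
  class(st) <- "clot_platelet_state"
  st
}

#' Bound and total platelet fractions
#'
#' `thetaB = (P_ba + P_sea) / P_max` drives the Darcy resistance;
#' `thetaT = (P_mu + P_ma + P_ba + P_sea) / P_max` is the argument of the
#' hindrance function.
#'
#' @param state a `clot_platelet_state`
#' @return list with `theta_B` and `theta_T` matrices
#' @export
compute_fractions <- function(state) {
  stopifnot(state$P_max > 0)
  bound <- state$P_ba + state$P_sea
  list(theta_B = bound / state$P_max,
       theta_T = (state$P_mu + state$P_ma + bound) / state$P_max)
}

#' Hindered-transport function W
#'
#' Smooth, non-increasing multiplier applied to the platelet flux:
#' `W(thetaT) = tanh(pi * (1 - thetaT)) / tanh(pi)` for `thetaT < 1` and 0
#' otherwise, so `W(0) = 1` exactly and all platelet transport shuts off at
#' the packing limit.
#'
#' @param theta_T total platelet fraction (any shape)
#' @return multiplier in \[0, 1\], same shape
#' @export
hindrance_W <- function(theta_T) {
  w <- tanh(pi * (1 - theta_T)) / tanh(pi)
  w[theta_T >= 1] <- 0
  w[theta_T <= 0] <- 1
  w
}

#' Binding-affinity function g
#'
#' Saturating (Hill-type) multiplier `g(eta) = eta / (eta_star + eta)` of the
#' cohesion rate, with `eta` a chemical signal (platelet-bound thrombin by
#' default in the shipped cases).  Set `bypass = TRUE` for `g == 1`.
#'
#' @param eta signal concentration (nM, any shape)
#' @param eta_star half-saturation concentration (nM)
#' @param bypass if `TRUE`, returns 1 everywhere
#' @return non-negative multiplier
#' @export
binding_affinity_g <- function(eta, eta_star, bypass = FALSE) {
  if (bypass) return(array(1, dim = dim(eta) %||% length(eta)))
  eta / (eta_star + eta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Agonist-driven activation rate (Hill kinetics)
#'
#' `A(c) = k_pla * c / (c_star + c)`.
#'
#' @param c agonist concentration (nM, any shape)
#' @param k_pla maximal activation rate (1/s)
#' @param c_star half-maximal concentration (nM)
#' @return activation rate (1/s)
#' @export
activation_rate <- function(c, k_pla, c_star) k_pla * c / (c_star + c)

#' Platelet state-transition source terms
#'
#' Computes `dP/dt` for the four platelet species from activation, wall
#' adhesion and cohesion.  All transfers are antisymmetric between states, so
#' the total platelet number is conserved exactly; adhesion is confined to
#' the wall-adhesion region and capped by a subendothelial site density, and
#' all binding terms carry the saturation factor `max(0, 1 - thetaT)` so they
#' vanish at the packing limit.
#'
#' @param state a `clot_platelet_state`
#' @param adhesion a `clot_adhesion_region`
#' @param g_value per-cell cohesion affinity multiplier (from
#'   [binding_affinity_g()])
#' @param agonist_rate per-cell total activation rate (1/s), i.e.
#'   `A_ADP(ADP) + A_E2(E2)`
#' @param params list with rate constants `k_adh` (1/s), `k_coh` (1/s) and
#'   `se_cap_density` (platelets/um^3, adhesion capacity of the wall cells)
#' @return list of matrices `P_mu`, `P_ma`, `P_ba`, `P_sea` with the
#'   respective `dP/dt` (platelets/um^3/s)
#' @export
platelet_sources <- function(state, adhesion, g_value, agonist_rate, params) {
  for (k in c("k_adh", "k_coh", "se_cap_density"))
    if (is.null(params[[k]]) || params[[k]] < 0)
      stop("configuration error: missing or negative platelet rate constant '", k, "'")
  fr <- compute_fractions(state)
  sat <- pmax(0, 1 - fr$theta_T)
  se_room <- pmax(0, 1 - state$P_sea / params$se_cap_density)
  adh <- params$k_adh * adhesion$indicator * sat * se_room
  coh <- params$k_coh * g_value * fr$theta_B * sat
  act <- agonist_rate

  d_mu <- -act * state$P_mu - adh * state$P_mu
  d_ma <- act * state$P_mu - adh * state$P_ma - coh * state$P_ma
  d_ba <- coh * state$P_ma
  d_sea <- adh * (state$P_mu + state$P_ma)
  list(P_mu = d_mu, P_ma = d_ma, P_ba = d_ba, P_sea = d_sea)
}

#' Hindered transport step for the mobile platelet species
#'
#' Advances `P_mu` and `P_ma` by one conservative transport step in which the
#' advective face flux is scaled by `W` of the *downwind*-interpolated total
#' platelet fraction and the diffusive face flux by `W` of the
#' *local-maximum*-interpolated fraction; this combination prevents any
#' transport of platelets into cells at the packing limit.  Bound species are
#' untouched (they are immobile); sources are handled separately in the
#' reaction stage of the fractional-step scheme.
#'
#' @param state a `clot_platelet_state`
#' @param flux face-flux list from [face_flux_field()]
#' @param dt time step (s)
#' @param mesh a `clot_mesh`
#' @param bc named list with elements `P_mu`, `P_ma`, each a per-patch
#'   boundary spec as in [advance_transport()]
#' @param cache environment reused across steps (holds the shared implicit
#'   diffusion factorisation for both mobile species)
#' @return list with the updated state and per-species boundary-influx
#'   accounting (`bnd_in`, platelets/s summed over both mobile species)
#' @export
hindered_platelet_step <- function(state, flux, dt, mesh, bc, cache = NULL) {
  if (is.null(cache)) cache <- new_transport_cache()
  fr <- compute_fractions(state)
  thT <- fr$theta_T
  th_adv <- interpolate_to_faces(thT, "downwind", flux, mesh)
  th_diff <- interpolate_to_faces(thT, "localMax", NULL, mesh)
  hind <- list(adv = list(x = hindrance_W(th_adv$x), y = hindrance_W(th_adv$y)),
               diff = list(x = hindrance_W(th_diff$x), y = hindrance_W(th_diff$y)))
  same_kinds <- identical(lapply(bc$P_mu, `[[`, "kind"),
                          lapply(bc$P_ma, `[[`, "kind"))
  if (same_kinds) {
    r <- advance_transport_block(list(P_mu = state$P_mu, P_ma = state$P_ma),
                                 flux, state$D_P, dt, mesh,
                                 list(bc$P_mu, bc$P_ma),
                                 hindrance = hind, cache = cache,
                                 cfl = "silent", diffusion = "explicit")
    state$P_mu <- r$values$P_mu
    state$P_ma <- r$values$P_ma
    bnd <- sum(r$bnd_adv_in) + sum(r$bnd_diff_in)
  } else {
    bnd <- 0
    for (sp in c("P_mu", "P_ma")) {
      if (is.null(cache[[sp]])) cache[[sp]] <- new_transport_cache()
      r <- advance_transport_block(list(state[[sp]]), flux, state$D_P, dt,
                                   mesh, list(bc[[sp]]), hindrance = hind,
                                   cache = cache[[sp]], cfl = "silent",
                                   diffusion = "explicit")
      state[[sp]] <- r$values[[1]]
      bnd <- bnd + r$bnd_adv_in + r$bnd_diff_in
    }
  }
  list(state = state, bnd_in = bnd)
}
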