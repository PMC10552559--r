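#' Channel thrombosis scenario and solver loop
#'
#' The shipped case is a 240 um x 60 um rectangular channel with an
#' approximately 90 um adhesive/reactive patch centred on the bottom wall,
#' meshed from three blocks so the middle block's bottom edge is the
#' `injuryWalls` patch.  The full case uses a uniform 128 x 32 mesh; the
#' reduced case the same geometry at 96 x 24 cells (cell size 2.5 um, still
#' below the platelet diameter) with a shorter end time.
#'
#' @name channel_case
NULL

#' Generate the channel thrombosis case
#'
#' @param scale `"full"` (128 x 32 cells, 600 s) or `"reduced"` (96 x 24
#'   cells, 30 s)
#' @param injury if `FALSE`, the middle bottom edge is an ordinary wall and
#'   coagulation/adhesion never initiates (control case)
#' @return list with `mesh` (a `clot_mesh`) and `config` (list with
#'   `mesh_spec`, `end_time`, `injury`, `with_inhibitor`, `params`)
#' @export
generate_channel_case <- function(scale = c("full", "reduced"),
                                  injury = TRUE) {
  scale <- match.arg(scale)
  ncell <- switch(scale,
    full = list(nx = c(40L, 48L, 40L), ny = 32L),
    reduced = list(nx = c(30L, 36L, 30L), ny = 24L))
  blocks <- list(
    list(x0 = 0, x1 = 75, y0 = 0, y1 = 60, nx = ncell$nx[1], ny = ncell$ny),
    list(x0 = 75, x1 = 165, y0 = 0, y1 = 60, nx = ncell$nx[2], ny = ncell$ny),
    list(x0 = 165, x1 = 240, y0 = 0, y1 = 60, nx = ncell$nx[3], ny = ncell$ny))
  pa <- c("1.west" = "inlet", "3.east" = "outlet",
          "1.south" = "walls", "3.south" = "walls",
          "2.south" = if (injury) "injuryWalls" else "walls",
          "1.north" = "walls", "2.north" = "walls", "3.north" = "walls")
  mesh <- build_multiblock_mesh(blocks, pa)
  config <- list(
    mesh_spec = list(blocks = blocks, patch_assignments = pa),
    end_time = switch(scale, full = 600, reduced = 30),
    injury = injury,
    with_inhibitor = FALSE,
    params = default_parameters())
  list(mesh = mesh, config = config)
}

## parabolic inlet profile with the configured wall shear rate
inlet_profile <- function(mesh, shear) {
  y0 <- min(mesh$y_faces); H <- diff(range(mesh$y_faces))
  function(y) shear / H * (y - y0) * (H - (y - y0))
}

#' Initialise a full simulation state
#'
#' Builds all coupled sub-states (fluid, platelets, chemistry, ADP release
#' history) and solver caches for a case.
#'
#' @param mesh a `clot_mesh`
#' @param config case configuration as returned by
#'   [generate_channel_case()]
#' @return a list-based simulation state (class `clot_sim_state`)
#' @export
new_simulation_state <- function(mesh, config) {
  p <- validate_parameters(config$params)
  injury <- isTRUE(config$injury) && "injuryWalls" %in% names(mesh$patches)
  if (injury) {
    vr <- validate_injury_resolution(mesh, p$Pdiam)
    if (!vr$pass)
      stop("mesh fails injury-resolution validation: ",
           nrow(vr$violations), " cell(s) larger than Pdiam")
  }
  sigma_every <- round(p$sigma_dt / p$dt)
  if (abs(sigma_every * p$dt - p$sigma_dt) > 1e-9)
    stop("configuration error: sigma_dt must be an integer multiple of dt")

  registry <- register_reduced_model(p)
  if (isTRUE(config$with_inhibitor))
    registry <- add_inhibitor_extension(registry, p$k_I)

  adhesion <- compute_adhesion_region(mesh, p$Pdiam, enabled = injury)
  fbc <- build_fluid_bc(mesh, inflow = list(
    inlet = inlet_profile(mesh, p$wall_shear_rate)))

  z <- matrix(0, mesh$nx, mesh$ny)
  chem <- list(S1 = z + p$S1_inlet, E1 = z, S2 = z + p$S2_inlet, E2 = z,
               I1 = z + p$I1_inlet, I2 = z + p$I2_inlet, E1I1 = z, E2I2 = z,
               E1b = z, S2b = z, E2b = z)
  inlet_conc <- c(S1 = p$S1_inlet, E1 = 0, S2 = p$S2_inlet, E2 = 0,
                  I1 = p$I1_inlet, I2 = p$I2_inlet, E1I1 = 0, E2I2 = 0)
  if (isTRUE(config$with_inhibitor)) {
    chem$I <- z + p$I_inlet; chem$E2_inh <- z
    inlet_conc <- c(inlet_conc, I = p$I_inlet, E2_inh = 0)
  }
  transported_chem <- names(inlet_conc)
  if (!p$eta_source %in% names(chem))
    stop("configuration error: eta_source '", p$eta_source,
         "' is not a registered chemical species")

  species_bc <- function(value) {
    bc <- list(inlet = list(kind = "fixed_value", value = value),
               outlet = list(kind = "zero_gradient"),
               walls = list(kind = "zero_gradient"))
    if (injury) bc$injuryWalls <- list(kind = "zero_gradient")
    bc
  }
  bcs <- lapply(inlet_conc, species_bc)
  bcs$ADP <- species_bc(0)
  bcs$P_mu <- species_bc(p$P_mu_inlet)
  bcs$P_ma <- species_bc(0)

  inj <- if (injury) patch_face_segments(mesh, "injuryWalls") else NULL

  state <- list(
    mesh = mesh, config = config, params = p, registry = registry,
    adhesion = adhesion, fbc = fbc, injury = injury,
    injury_faces = inj,
    fluid = init_fluid_state(mesh, p$nu, p$rho),
    plt = init_platelet_state(mesh, p$P_max, p$D_P, P_mu0 = p$P_mu_inlet),
    chem = chem, adp = z,
    E0 = if (injury) rep(p$E0_init, nrow(inj)) else numeric(0),
    history = new_release_history(mesh, p$sigma_dt, p$sigma_Tf),
    sigma = z, theta_B_sample = z, t_sample = 0,
    bcs = bcs, transported_chem = transported_chem,
    t = 0, step = 0L, sigma_every = as.integer(sigma_every),
    ## budget accounting
    plt_total0 = NA_real_, plt_bnd_cum = 0, plt_clip_cum = 0,
    chem_clip_cum = 0, max_theta_T = 0,
    caches = list())
  state$plt_total0 <- platelet_total(state)
  class(state) <- "clot_sim_state"
  state
}

platelet_total <- function(state) {
  sum((state$plt$P_mu + state$plt$P_ma + state$plt$P_ba + state$plt$P_sea) *
        state$mesh$cell_volumes)
}

## reaction-stage derivative over chem + platelet fields; ADP is frozen input
reaction_derivative <- function(state, adp_frozen) {
  p <- state$params
  reg <- state$registry
  adh <- state$adhesion
  inj <- state$injury_faces
  E0 <- state$E0
  V <- state$mesh$cell_volumes
  a_adp <- activation_rate(adp_frozen, p$k_pla_adp, p$c_star_adp)
  idx <- if (!is.null(inj)) cbind(inj$i, inj$j) else NULL
  wall_scale <- if (!is.null(inj)) inj$length / V[idx] else NULL
  function(f) {
    out <- network_rates(reg, f, P_bound = f$P_ba + f$P_sea)
    if (!is.null(idx)) {
      sr <- se_surface_reaction(pmax(f$S1[idx], 0), E0, p)
      dS1 <- 0 * f$S1
      dS1[idx] <- sr$S1_flux * wall_scale
      out$S1 <- if (is.null(out$S1)) dS1 else out$S1 + dS1
      dE1 <- sr$E1_flux * wall_scale
      out$E1[idx] <- out$E1[idx] + dE1
    }
    agonist <- a_adp + activation_rate(pmax(f$E2, 0), p$k_pla_e2, p$c_star_e2)
    g <- binding_affinity_g(pmax(f[[p$eta_source]], 0), p$eta_star,
                            bypass = p$g_bypass > 0)
    ps <- platelet_sources(list(P_mu = f$P_mu, P_ma = f$P_ma, P_ba = f$P_ba,
                                P_sea = f$P_sea, P_max = p$P_max),
                           adh, g, agonist, p)
    out[names(ps)] <- ps
    out
  }
}

#' Advance a simulation state by one fractional-step cycle
#'
#' One full time step of the coupled system: (1) Carman-Kozeny resistance
#' from the previous step's bound fraction; (2) momentum predictor and PISO
#' correctors; (3) hindered platelet transport and fluid-phase chemical
#' transport; (4) `M_rxn` coupled RK4 reaction sub-steps (cascade kinetics,
#' platelet state transitions, injured-wall surface reaction); (5) release
#' history / ADP source update at the `sigma_dt` cadence; (6) ADP transport
#' step with its release source.
#'
#' @param state a `clot_sim_state`
#' @param transport if `FALSE`, skip fluid+transport (well-mixed reaction
#'   stepping only)
#' @param react if `FALSE`, skip the reaction stage (pure transport)
#' @return the advanced state
#' @export
fractional_step <- function(state, transport = TRUE, react = TRUE) {
  p <- state$params; mesh <- state$mesh; dt <- p$dt
  fr <- compute_fractions(state$plt)
  state$max_theta_T <- max(state$max_theta_T, max(fr$theta_T))

  if (transport) {
    alpha <- carman_kozeny_alpha(fr$theta_B, p$C_CK)
    if (is.null(state$caches$fluid)) state$caches$fluid <- new_fluid_cache()
    state$fluid <- advance_fluid(state$fluid, alpha, dt, mesh, state$fbc,
                                 state$caches$fluid, p$n_correctors)
    flux <- face_flux_field(state$fluid$u, state$fluid$v, mesh)

    if (is.null(state$caches$plt)) state$caches$plt <- new_transport_cache()
    hp <- hindered_platelet_step(state$plt, flux, dt, mesh,
                                 list(P_mu = state$bcs$P_mu,
                                      P_ma = state$bcs$P_ma),
                                 state$caches$plt)
    state$plt <- hp$state
    state$plt_bnd_cum <- state$plt_bnd_cum + hp$bnd_in * dt

    if (is.null(state$caches$chem)) state$caches$chem <- new_transport_cache()
    tc <- state$transported_chem
    r <- advance_transport_block(state$chem[tc], flux, p$D_c, dt, mesh,
                                 state$bcs[tc], cache = state$caches$chem,
                                 cfl = "silent")
    state$chem[tc] <- r$values
  } else {
    flux <- NULL
  }

  if (react) {
    fields <- c(state$chem,
                list(P_mu = state$plt$P_mu, P_ma = state$plt$P_ma,
                     P_ba = state$plt$P_ba, P_sea = state$plt$P_sea))
    deriv <- reaction_derivative(state, state$adp)
    fields <- rk4_react(fields, deriv, h = dt / p$M_rxn, n_steps = p$M_rxn)
    for (sp in names(state$chem)) state$chem[[sp]] <- fields[[sp]]
    for (sp in c("P_mu", "P_ma", "P_ba", "P_sea")) state$plt[[sp]] <- fields[[sp]]
  }

  ## clip transport/reaction undershoots; log the clipped mass
  for (sp in names(state$chem)) {
    x <- state$chem[[sp]]
    neg <- x < 0
    if (any(neg)) {
      state$chem_clip_cum <- state$chem_clip_cum - sum(x[neg] * mesh$cell_volumes[neg])
      x[neg] <- 0
      state$chem[[sp]] <- x
    }
  }
  for (sp in c("P_mu", "P_ma", "P_ba", "P_sea")) {
    x <- state$plt[[sp]]
    neg <- x < 0
    if (any(neg)) {
      state$plt_clip_cum <- state$plt_clip_cum - sum(x[neg] * mesh$cell_volumes[neg])
      x[neg] <- 0
      state$plt[[sp]] <- x
    }
  }

  state$t <- state$t + dt
  state$step <- state$step + 1L

  ## release-history update at the sigma_dt cadence, then the ADP step
  if (state$step %% state$sigma_every == 0L) {
    fr2 <- compute_fractions(state$plt)
    B <- newly_bound_rate(fr2$theta_B, state$theta_B_sample,
                          state$t, state$t_sample, p$P_max)
    state$history <- push_release_history(state$history, B, state$t)
    state$sigma <- sigma_release(state$history, p$A_hat)$sigma
    state$theta_B_sample <- fr2$theta_B
    state$t_sample <- state$t
  }
  if (transport) {
    if (is.null(state$caches$ADP)) state$caches$ADP <- new_transport_cache()
    r <- advance_adp(state$adp, flux, state$sigma, p$D_ADP, dt, mesh,
                     state$bcs$ADP, state$caches$ADP)
    state$adp <- pmax(r$values, 0)
  } else {
    state$adp <- pmax(state$adp + state$sigma * dt, 0)
  }
  state
}

#' Run a simulation
#'
#' Marches the coupled system from `t = 0` (or from a checkpointed state) to
#' `config$end_time`, recording field snapshots and scalar diagnostics at the
#' configured output cadence.  The method contains no randomness: two runs
#' with the same configuration produce identical outputs.
#'
#' @param mesh a `clot_mesh`
#' @param config case configuration (see [generate_channel_case()])
#' @param init_state optional checkpointed state (from a previous bundle's
#'   `final_state`) to resume from
#' @param end_time optional override of `config$end_time`
#' @param verbose print progress lines
#' @return class `clot_output_bundle`: `times`, `snapshots` (field sets),
#'   `series` (data frame of scalar diagnostics), `config`, `mesh`,
#'   `final_state`
#' @export
run_simulation <- function(mesh, config, init_state = NULL,
                           end_time = NULL, verbose = FALSE) {
  state <- if (is.null(init_state)) new_simulation_state(mesh, config)
           else init_state
  state$caches <- list()          # caches are rebuilt, not part of a checkpoint
  p <- state$params
  t_end <- end_time %||% config$end_time
  out_every <- max(1L, round(p$output_interval / p$dt))
  n_steps <- round((t_end - state$t) / p$dt)

  snapshots <- list()
  rows <- list()
  take_snapshot <- function(state) {
    fr <- compute_fractions(state$plt)
    list(t = state$t, u = state$fluid$u, v = state$fluid$v, p = state$fluid$p,
         theta_B = fr$theta_B, theta_T = fr$theta_T,
         P_mu = state$plt$P_mu, P_ma = state$plt$P_ma,
         P_ba = state$plt$P_ba, P_sea = state$plt$P_sea,
         adp = state$adp, chem = state$chem, E0 = state$E0)
  }
  record <- function(state) {
    fr <- compute_fractions(state$plt)
    tot <- platelet_total(state)
    resid <- (tot - state$plt_total0 - state$plt_bnd_cum + state$plt_clip_cum) /
      max(state$plt_total0, tot)
    thrombin <- sum((state$chem$E2 + state$chem$E2b) * state$mesh$cell_volumes)
    clot <- sum(state$mesh$cell_volumes[fr$theta_B >= p$clot_threshold])
    data.frame(time = state$t, max_theta_T = max(fr$theta_T),
               run_max_theta_T = state$max_theta_T,
               platelet_total = tot, budget_residual = resid,
               clipped_platelets = state$plt_clip_cum,
               total_thrombin = thrombin, clot_area = clot,
               max_div = state$fluid$max_div %||% NA_real_)
  }
  snapshots[[1]] <- take_snapshot(state)
  rows[[1]] <- record(state)

  for (s in seq_len(n_steps)) {
    state <- tryCatch(fractional_step(state), error = function(e) {
      dump <- file.path(tempdir(), sprintf("clotsim-crash-t%.4f.rds", state$t))
      saveRDS(state, dump)
      stop("solver failure at t = ", format(state$t), ": ",
           conditionMessage(e), "\n  state dumped to ", dump, call. = FALSE)
    })
    if (state$step %% out_every == 0L || s == n_steps) {
      snapshots[[length(snapshots) + 1L]] <- take_snapshot(state)
      rows[[length(rows) + 1L]] <- record(state)
      if (verbose)
        message(sprintf("t = %.3f s  max(thetaT) = %.4f  div = %.2e",
                        state$t, max(compute_fractions(state$plt)$theta_T),
                        state$fluid$max_div))
    }
  }
  fr <- compute_fractions(state$plt)
  state$max_theta_T <- max(state$max_theta_T, max(fr$theta_T))

  bundle <- list(times = vapply(snapshots, `[[`, 0, "t"),
                 snapshots = snapshots,
                 series = do.call(rbind, rows),
                 config = config, mesh = mesh,
                 final_state = state)
  class(bundle) <- "clot_output_bundle"
  bundle
}

#' @exportS3Method base::print
print.clot_output_bundle <- function(x, ...) {
  cat("clot_output_bundle:", length(x$times), "snapshots, t in [",
      min(x$times), ",", max(x$times), "] s\n")
  invisible(x)
}

#' Clot growth and thrombin metrics
#'
#' @param bundle a `clot_output_bundle`
#' @param theta_threshold bound-fraction threshold defining "clot" cells
#'   (reporting convention; default 0.5)
#' @return data frame: `time`, `clot_area` (um^2 of cells with
#'   `thetaB >= threshold`), `mean_clot_density` (mean thetaB over those
#'   cells, 0 if none) and `total_thrombin` (integral of E2 + E2b, nM um^3)
#' @export
clot_metrics <- function(bundle, theta_threshold = 0.5) {
  V <- bundle$mesh$cell_volumes
  rows <- lapply(bundle$snapshots, function(sn) {
    if (is.null(sn$theta_B) || is.null(sn$chem$E2) || is.null(sn$chem$E2b))
      stop("bundle snapshots lack thetaB/E2/E2b fields")
    inclot <- sn$theta_B >= theta_threshold
    data.frame(time = sn$t,
               clot_area = sum(V[inclot]),
               mean_clot_density = if (any(inclot)) mean(sn$theta_B[inclot]) else 0,
               total_thrombin = sum((sn$chem$E2 + sn$chem$E2b) * V))
  })
  do.call(rbind, rows)
}
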