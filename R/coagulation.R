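#' Reduced platelet-surface-mediated coagulation cascade
#'
#' A twelve-species reduction of the coagulation network, with species
#' tagged by where they live: `fluidPhase` species advect and diffuse,
#' `pltBound` species are attached to activated-platelet surfaces (immobile,
#' with saturable binding-site capacities that scale with the local bound
#' platelet density), and `seBound` species live only on the injured-wall
#' patch.  The wiring follows the cascade's initiation-amplification logic:
#' a subendothelial enzyme E0 converts fluid substrate S1 to enzyme E1 at
#' the injured wall; E1 binds to activated platelets (E1b); fluid substrate
#' S2 binds as S2b; E1b activates S2b into the thrombin-like bound enzyme
#' E2b, which also activates S2b in a positive feedback loop; E2b releases
#' fluid-phase thrombin E2, which activates mobile platelets; fluid-phase
#' inhibitors I1 and I2 irreversibly neutralise E1 and E2 into the inert
#' complexes E1I1 and E2I2 (bound enzymes are protected from inhibition).
#'
#' Species split (12): fluidPhase S1, E1, S2, E2, I1, I2, E1I1, E2I2;
#' pltBound E1b, S2b, E2b; seBound E0.
#'
#' @name coagulation_network
NULL

COAG_FLUID_SPECIES <- c("S1", "E1", "S2", "E2", "I1", "I2", "E1I1", "E2I2")
COAG_PLT_SPECIES <- c("E1b", "S2b", "E2b")
COAG_SE_SPECIES <- c("E0")
COAG_RATE_KEYS <- c("kon1", "koff1", "kon2", "koff2", "kact1", "kact_fb",
                    "koff_e2", "ki1", "ki2", "N1_sites", "N2_sites",
                    "kcat0", "KM0")

#' Register the reduced coagulation model
#'
#' Builds the category-tagged species registry for the default twelve-species
#' cascade plus the four platelet species and ADP, and attaches the
#' mass-action reaction system.  All rate constants must be present and
#' non-negative.
#'
#' @param params named list of rate constants: `kon1`, `koff1` (E1 platelet
#'   binding, 1/(nM s) and 1/s), `kon2`, `koff2` (S2 binding), `kact1`
#'   (S2b activation by E1b, 1/(nM s)), `kact_fb` (feedback activation by
#'   E2b), `koff_e2` (thrombin release from the platelet surface, 1/s),
#'   `ki1`, `ki2` (inhibition of fluid E1 and E2, 1/(nM s)), `N1_sites`,
#'   `N2_sites` (binding sites per platelet), `kcat0` (1/s) and `KM0` (nM)
#'   for the subendothelial S1 -> E1 conversion
#' @return class `clot_species_registry`
#' @export
register_reduced_model <- function(params) {
  missing <- COAG_RATE_KEYS[!COAG_RATE_KEYS %in% names(params)]
  if (length(missing) > 0)
    stop("configuration error: missing rate constant(s): ",
         paste(missing, collapse = ", "))
  for (k in COAG_RATE_KEYS)
    if (!is.finite(params[[k]]) || params[[k]] < 0)
      stop("configuration error: rate constant '", k, "' must be finite and >= 0")

  entry <- function(name, category, group, transported)
    list(name = name, category = category, group = group,
         transported = transported)
  species <- c(
    lapply(COAG_FLUID_SPECIES, entry, category = "fluidPhase",
           group = "coagulation", transported = TRUE),
    lapply(COAG_PLT_SPECIES, entry, category = "pltBound",
           group = "coagulation", transported = FALSE),
    lapply(COAG_SE_SPECIES, entry, category = "seBound",
           group = "coagulation", transported = FALSE),
    lapply(c("P_mu", "P_ma"), entry, category = "platelet",
           group = "platelet", transported = TRUE),
    lapply(c("P_ba", "P_sea"), entry, category = "platelet",
           group = "platelet", transported = FALSE),
    list(entry("ADP", "fluidPhase", "agonist", transported = TRUE)))
  names(species) <- vapply(species, `[[`, "", "name")

  reg <- list(species = species, params = params,
              reactions = list(base = base_coagulation_rates))
  class(reg) <- "clot_species_registry"
  reg
}

#' Species counts by group and category
#'
#' @param registry a `clot_species_registry`
#' @return list with `coagulation` (should be 12 for the base model),
#'   `platelet`, `agonist`, `platelet_side_adr` (platelet species + ADP) and
#'   a `by_category` table
#' @export
species_counts <- function(registry) {
  grp <- vapply(registry$species, `[[`, "", "group")
  cat_ <- vapply(registry$species, `[[`, "", "category")
  list(coagulation = sum(grp == "coagulation"),
       platelet = sum(grp == "platelet"),
       agonist = sum(grp == "agonist"),
       platelet_side_adr = sum(grp %in% c("platelet", "agonist")),
       by_category = table(cat_))
}

#' @exportS3Method base::print
print.clot_species_registry <- function(x, ...) {
  sc <- species_counts(x)
  cat("clot_species_registry:", sc$coagulation, "coagulation species,",
      sc$platelet, "platelet species,", sc$agonist, "agonist;",
      length(x$reactions), "reaction block(s)\n")
  invisible(x)
}

## Platelet-surface binding capacities (nM) from bound platelet densities.
binding_site_caps <- function(P_bound, params) {
  conc <- P_bound * PLT_UM3_TO_NM
  list(sites1 = params$N1_sites * conc, sites2 = params$N2_sites * conc)
}

## Bulk mass-action rates of the base cascade.  `conc` is a named list of
## same-shaped arrays; returns derivative contributions for the species it
## touches.  S1 has no bulk reactions (its conversion happens at the wall).
base_coagulation_rates <- function(conc, params, caps) {
  free1 <- pmax(0, caps$sites1 - conc$E1b)
  free2 <- pmax(0, caps$sites2 - conc$S2b - conc$E2b)
  v_on1 <- params$kon1 * conc$E1 * free1
  v_off1 <- params$koff1 * conc$E1b
  v_on2 <- params$kon2 * conc$S2 * free2
  v_off2 <- params$koff2 * conc$S2b
  v_act <- (params$kact1 * conc$E1b + params$kact_fb * conc$E2b) * conc$S2b
  v_rel <- params$koff_e2 * conc$E2b
  v_i1 <- params$ki1 * conc$E1 * conc$I1
  v_i2 <- params$ki2 * conc$E2 * conc$I2
  list(E1 = -v_on1 + v_off1 - v_i1,
       E1b = v_on1 - v_off1,
       S2 = -v_on2 + v_off2,
       S2b = v_on2 - v_off2 - v_act,
       E2b = v_act - v_rel,
       E2 = v_rel - v_i2,
       I1 = -v_i1, E1I1 = v_i1,
       I2 = -v_i2, E2I2 = v_i2)
}

#' Add the irreversible thrombin-inhibitor extension
#'
#' Demonstrates the two-step extension recipe: a new fluid-phase species `I`
#' that inhibits fluid-phase thrombin indefinitely, `I + E2 -> E2_inh` with
#' rate `k_I * I * E2`, adding the inert product `E2_inh`.
#'
#' @param registry a `clot_species_registry`
#' @param k_I association rate (1/(nM s))
#' @return the extended registry
#' @export
add_inhibitor_extension <- function(registry, k_I) {
  if (any(c("I", "E2_inh") %in% names(registry$species)))
    stop("species name collision: 'I'/'E2_inh' already registered")
  stopifnot(is.finite(k_I), k_I >= 0)
  entry <- function(name) list(name = name, category = "fluidPhase",
                               group = "coagulation", transported = TRUE)
  registry$species$I <- entry("I")
  registry$species$E2_inh <- entry("E2_inh")
  registry$params$k_I <- k_I
  registry$reactions$inhibitor <- function(conc, params, caps) {
    v <- params$k_I * conc$I * conc$E2
    list(I = -v, E2 = -v, E2_inh = v)
  }
  registry
}

#' Evaluate the coupled network right-hand side
#'
#' Sums all registered reaction blocks for a set of concentration arrays.
#'
#' @param registry a `clot_species_registry`
#' @param conc named list of concentration arrays (nM); must include every
#'   coagulation species the reaction blocks touch
#' @param P_bound bound platelet density `P_ba + P_sea` (platelets/um^3),
#'   same shape, determining the platelet binding-site capacities
#' @return named list of `dC/dt` (nM/s) for all touched species
#' @export
network_rates <- function(registry, conc, P_bound = 0) {
  caps <- binding_site_caps(P_bound, registry$params)
  out <- list()
  for (fn in registry$reactions) {
    contrib <- fn(conc, registry$params, caps)
    for (nm in names(contrib))
      out[[nm]] <- if (is.null(out[[nm]])) contrib[[nm]] else out[[nm]] + contrib[[nm]]
  }
  out
}

#' Subendothelial surface reaction at the injured wall
#'
#' Michaelis-type conversion of fluid substrate S1 into enzyme E1 by the
#' wall-bound enzyme E0: flux density `phi = kcat0 * E0 * S1 / (KM0 + S1)`.
#' The S1 consumption flux equals the E1 production flux exactly (1:1
#' conversion), and both vanish where E0 = 0.
#'
#' @param S1_wall S1 concentration in the wall-adjacent cells (nM), per face
#' @param E0_density wall enzyme surface density per face (nM um)
#' @param params list with `kcat0` (1/s) and `KM0` (nM)
#' @return list with `S1_flux` (negative: consumption, nM um/s) and
#'   `E1_flux` (positive: production), per face
#' @export
se_surface_reaction <- function(S1_wall, E0_density, params) {
  if (any(E0_density < 0)) stop("E0 surface density must be non-negative")
  phi <- params$kcat0 * E0_density * S1_wall / (params$KM0 + S1_wall)
  list(S1_flux = -phi, E1_flux = phi)
}

## list arithmetic for RK4 over named lists of arrays
list_axpy <- function(y, k, a) {
  out <- y
  for (nm in names(k)) out[[nm]] <- y[[nm]] + a * k[[nm]]
  out
}

#' Coupled classical RK4 integration of reaction equations
#'
#' Advances a named list of state arrays through `n_steps` steps of size `h`
#' of the classical fourth-order Runge-Kutta method, with all species
#' advanced simultaneously (coupled stages, not sequential).
#'
#' @param fields named list of arrays (the state)
#' @param deriv function `fields -> named list of dX/dt` (entries may cover
#'   a subset of the state; untouched entries are held constant).  Build one
#'   for a registry with [registry_derivative()] or pass any side-effect-free
#'   function for generic ODE systems.
#' @param h stage step size (s)
#' @param n_steps number of RK4 steps
#' @return the advanced state list
#' @export
rk4_react <- function(fields, deriv, h, n_steps = 1L) {
  stopifnot(h > 0, n_steps >= 1)
  for (s in seq_len(n_steps)) {
    k1 <- deriv(fields)
    k2 <- deriv(list_axpy(fields, k1, h / 2))
    k3 <- deriv(list_axpy(fields, k2, h / 2))
    k4 <- deriv(list_axpy(fields, k3, h))
    for (nm in names(k1))
      fields[[nm]] <- fields[[nm]] +
        (h / 6) * (k1[[nm]] + 2 * k2[[nm]] + 2 * k3[[nm]] + k4[[nm]])
    for (nm in names(k1))
      if (!all(is.finite(fields[[nm]])))
        stop("non-finite value for species '", nm, "' at cell ",
             which(!is.finite(fields[[nm]]))[1], " during RK4 step ", s)
  }
  fields
}

#' Build the well-mixed (0-D) reaction derivative for a registry
#'
#' Returns a closure suitable for [rk4_react()] or as an oracle input to an
#' independent ODE solver; operates on scalar (or uniform-array)
#' concentrations with a fixed bound-platelet density.
#'
#' @param registry a `clot_species_registry`
#' @param P_bound bound platelet density (platelets/um^3)
#' @return function mapping a named state list to its derivative
#' @export
registry_derivative <- function(registry, P_bound = 0) {
  force(P_bound)
  function(fields) network_rates(registry, fields, P_bound)
}

#' Thrombin generation curve diagnostics
#'
#' Summarises a total-thrombin time course (E2 + E2b) from a well-mixed run:
#' plateau, lag time (first time reaching 10% of plateau), maximum production
#' rate and its timing, and a burst ("sigmoidal") flag.  A curve is flagged
#' as a burst when the maximum rate occurs after the lag time *and* the rise
#' is concentrated: `max_rate * (t90 - t10) / (0.8 * plateau) >= 1.5`, i.e.
#' the peak rate is at least 1.5x the average rate over the 10-90% rise.
#' A non-monotone plateau is flagged (not fatal).
#'
#' @param times time points (s)
#' @param thrombin total thrombin (nM) at `times`
#' @return list with `lag_time`, `max_rate`, `t_max_rate`, `plateau`,
#'   `sigmoidal`, `monotone`
#' @export
thrombin_burst_diagnostics <- function(times, thrombin) {
  stopifnot(length(times) == length(thrombin), length(times) >= 3)
  plateau <- max(thrombin)
  if (plateau <= 0)
    return(list(lag_time = Inf, max_rate = 0, t_max_rate = NA_real_,
                plateau = 0, sigmoidal = FALSE, monotone = TRUE))
  cross <- function(frac) times[which(thrombin >= frac * plateau)[1]]
  t10 <- cross(0.1); t90 <- cross(0.9)
  rate <- diff(thrombin) / diff(times)
  tmid <- (times[-1] + times[-length(times)]) / 2
  imax <- which.max(rate)
  shape <- max(rate) * (t90 - t10) / (0.8 * plateau)
  monotone <- all(rate >= -1e-9 * max(abs(thrombin)))
  list(lag_time = t10, max_rate = max(rate), t_max_rate = tmid[imax],
       plateau = plateau,
       sigmoidal = (tmid[imax] > t10) && shape >= 1.5,
       monotone = monotone)
}
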