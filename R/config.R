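#' Model and numerics parameters
#'
#' A single flat key-value dictionary configures the solver, mirroring the
#' style of an OpenFOAM `constant/inputParameters` dictionary (keys like
#' `sigma_dt`, `sigma_Tf`, `M_rxn`, `num_fluidPhase` keep those names).
#' Internal units: um, s, nM, platelets/um^3.
#'
#' @name scenario_io_cli
NULL

#' Default physical and numerical parameters
#'
#' Physiologically motivated defaults for the channel thrombosis cases.
#' Values the model prescribes structurally: platelet diameter `Pdiam` = 3 um,
#' reaction sub-steps `M_rxn` = 2, ADP release window `sigma_Tf` = 6 s,
#' Carman-Kozeny constant 10^6 mm^-2 (= 1 um^-2).
#'
#' @return named list of parameters
#' @export
default_parameters <- function() {
  list(
    ## fluid (blood plasma)
    nu = 1.2e6,            # kinematic viscosity (um^2/s)
    rho = 1,               # internal kinematic convention
    C_CK = 1,              # Carman-Kozeny constant (um^-2) = 1e6 mm^-2
    wall_shear_rate = 100, # inlet wall shear rate (1/s)
    n_correctors = 2,
    div_tolerance = 1e-8,  # normalised by U_ref/L_ref
    ## platelets
    P_max = 6.67e-2,       # packing limit (platelets/um^3)
    D_P = 25,              # effective platelet diffusivity (um^2/s)
    Pdiam = 3,             # platelet diameter (um)
    P_mu_inlet = 2.5e-4,   # inlet mobile-unactivated density (platelets/um^3)
    k_adh = 2,             # wall adhesion rate inside the adhesion region (1/s)
    k_coh = 10,            # cohesion rate scale (1/s)
    se_cap_density = 0.05, # subendothelial adhesion capacity (platelets/um^3)
    eta_star = 1,          # cohesion affinity half-saturation (nM)
    eta_source = "E2b",    # chemical driving the binding affinity g
    g_bypass = 0,          # 1: g == 1 (affinity bypassed)
    k_pla_adp = 0.34, c_star_adp = 1000,  # ADP activation Hill parameters
    k_pla_e2 = 0.5, c_star_e2 = 1,        # thrombin activation Hill parameters
    ## ADP release
    D_ADP = 250,           # ADP diffusivity (um^2/s)
    A_hat = 2.4e-17,       # ADP released per platelet (mol/platelet)
    sigma_dt = 0.05,       # release-history sampling interval (s)
    sigma_Tf = 6,          # release window (s)
    ## coagulation (12-species reduced cascade)
    num_fluidPhase = 8,
    D_c = 50,              # fluid-phase protein diffusivity (um^2/s)
    kon1 = 1e-2, koff1 = 5.7e-3,    # E1 platelet binding
    kon2 = 1e-2, koff2 = 5.9e-3,    # S2 platelet binding
    kact1 = 1e-4,          # S2b activation by E1b (1/(nM s))
    kact_fb = 1e-2,        # positive feedback: S2b activation by E2b
    koff_e2 = 0.2,         # thrombin release from the surface (1/s)
    ki1 = 1e-4, ki2 = 1e-4,         # fluid-phase inhibition rates
    N1_sites = 1000, N2_sites = 2000,  # binding sites per platelet
    kcat0 = 1, KM0 = 200,  # subendothelial S1 -> E1 conversion
    k_I = 1e-3,            # extension: irreversible thrombin inhibitor rate (1/(nM s))
    I_inlet = 100,         # extension: inhibitor inlet concentration (nM)
    E0_init = 10,          # wall enzyme surface density (nM um)
    S1_inlet = 170, S2_inlet = 1400,   # zymogen inlet concentrations (nM)
    I1_inlet = 50, I2_inlet = 2400,    # inhibitor inlet concentrations (nM)
    ## numerics
    dt = 1e-3,             # transport/fluid time step (s)
    M_rxn = 2,             # reaction sub-steps per transport step
    output_interval = 1,   # snapshot cadence (s)
    clot_threshold = 0.5   # thetaB threshold for the clot-area metric
  )
}

#' Read a flat key-value parameter file
#'
#' One `key value` pair per line; `#` starts a comment.  Unknown keys warn;
#' missing required keys are an error.
#'
#' @param path file path
#' @param required character vector of required keys (default: all keys of
#'   [default_parameters()])
#' @return named list (numeric where possible)
#' @export
read_input_parameters <- function(path,
                                  required = names(default_parameters())) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "[ \t]+")[[1]]
    if (length(parts) < 2) stop("malformed parameter line: '", ln, "'")
    key <- parts[1]
    val <- paste(parts[-1], collapse = " ")
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (is.na(num)) val else num
  }
  unknown <- setdiff(names(out), required)
  if (length(unknown) > 0)
    warning("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(required, names(out))
  if (length(missing) > 0)
    stop("missing required parameter key(s): ", paste(missing, collapse = ", "))
  out
}

#' Write a flat key-value parameter file
#'
#' @param params named list
#' @param path file path
#' @export
write_input_parameters <- function(params, path) {
  lines <- vapply(names(params), function(k) {
    v <- params[[k]]
    paste(k, if (is.numeric(v)) format(v, digits = 17) else as.character(v))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

## validate presence and positivity of the keys a run needs
validate_parameters <- function(params) {
  need_pos <- c("nu", "P_max", "D_P", "Pdiam", "dt", "M_rxn", "sigma_dt",
                "sigma_Tf", "n_correctors")
  missing <- setdiff(names(default_parameters()), names(params))
  if (length(missing) > 0)
    stop("missing required parameter key(s): ", paste(missing, collapse = ", "))
  for (k in need_pos)
    if (!is.numeric(params[[k]]) || params[[k]] <= 0)
      stop("parameter '", k, "' must be positive")
  invisible(params)
}
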