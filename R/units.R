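#' Internal unit system
#'
#' All spatial quantities are in micrometres, time in seconds, chemical
#' concentrations in nanomolar (nM) and platelet species in number densities
#' (platelets per cubic micrometre). A handful of conversion constants bridge
#' the two concentration conventions.
#'
#' @name clotsim-units
#' @keywords internal
NULL

## 1 platelet/um^3 expressed in nM:
##   (1/6.022e23) mol/um^3 = 1.6606e-24 mol/um^3; 1 nM = 1e-24 mol/um^3.
PLT_UM3_TO_NM <- 1e24 / 6.02214076e23

## 1 mol/um^3 expressed in nM (used for the ADP release unit bridge).
MOL_UM3_TO_NM <- 1e24

#' Convert a platelet number density to a molar concentration
#'
#' @param p number density (platelets/um^3)
#' @return concentration in nM
#' @keywords internal
plt_density_to_nM <- function(p) p * PLT_UM3_TO_NM
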