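#' Unit conventions and physical constants
#'
#' All lengths are micrometres, times are seconds (remodeling schedules are
#' configured in hours and converted once), volumes are \eqn{\mu m^3}.
#' Partial oxygen pressures are mmHg throughout; hydrodynamic pressures are
#' stored in mmHg at the nodes and converted to Pa inside the flow solver,
#' so wall shear stress comes out in Pa directly. Oxygen amounts are ml O2
#' (gas volume at STP); solubilities are mlO2 ml^-1 mmHg^-1.
#'
#' @format A named list of conversion factors and constants:
#' \describe{
#'   \item{mmHg_to_Pa}{133.322 Pa per mmHg.}
#'   \item{hour_to_s}{3600 s per hour.}
#'   \item{hb_molar_mass}{64500 g/mol, molar mass of the hemoglobin tetramer,
#'     used to express tissue hemoglobin concentrations in \eqn{\mu mol/l}.}
#'   \item{MCHC}{0.34 g/ml, mean corpuscular hemoglobin concentration.}
#'   \item{huefner}{1.36 mlO2 per g hemoglobin (binding capacity).}
#' }
#' @export
vasox_units <- list(
  mmHg_to_Pa   = 133.322,
  hour_to_s    = 3600,
  hb_molar_mass = 64500,
  MCHC         = 0.34,
  huefner      = 1.36
)
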