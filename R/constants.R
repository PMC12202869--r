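# CODATA 2018 exact values (SI); hc in eV nm derives from these.
.const <- list(
  h  = 6.62607015e-34,   # Planck constant, J s
  c  = 299792458,        # speed of light, m s^-1
  kB = 1.380649e-23,     # Boltzmann constant, J K^-1
  NA_mol = 6.02214076e23, # Avogadro constant, mol^-1
  e  = 1.602176634e-19,  # elementary charge, J eV^-1
  hc_ev_nm = 1239.841984 # h*c in eV nm
)

#' Reference photon-flux constants for hydrothermal-vent light budgets
#'
#' Named constants (all in photons cm^-2 s^-1 sr^-1) used when a computed
#' SHG photon budget is compared against observational and physiological
#' benchmarks:
#'
#' * `visible_blackbody_limit` (1e3): literature upper limit of thermal
#'   blackbody radiation in the 400-600 nm window at vents.  A cited
#'   external constant; its underlying temperature/emissivity assumptions
#'   are not restated, so it is never recomputed here.
#' * `observed_vent_visible` (1e4): visible-light (400-600 nm) photon flux
#'   recorded by in situ spectral cameras around vents.
#' * `ir_band_flux_400C` (1e12): order-of-magnitude 800-1100 nm photon flux
#'   of a 400 degC vent; the headline budget uses this printed constant by
#'   default (the package's own Planck integral gives ~9.3e12, switchable
#'   in [run_photon_budget()]).
#' * `low_light_requirement` (1e11): photon flux at which oxygenic
#'   photosynthesis has been shown to persist (0.04 umol photons m^-2 s^-1
#'   over a hemisphere).
#' * `lab_growth_requirement` (1e13): typical photon flux used for
#'   cyanobacterial laboratory growth; quoted without a stated derivation,
#'   stored as a named constant only.
#'
#' @format A named numeric vector of length 5.
#' @examples
#' flux_constants[["visible_blackbody_limit"]]
#' @export
flux_constants <- c(
  visible_blackbody_limit = 1e3,
  observed_vent_visible   = 1e4,
  ir_band_flux_400C       = 1e12,
  low_light_requirement   = 1e11,
  lab_growth_requirement  = 1e13
)
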