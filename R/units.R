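#' @keywords internal
"_PACKAGE"

# Physical constants used throughout. Molar volume follows the ideal gas law
# at the stated temperature and pressure; CH4 molar mass 16.04 g/mol is used
# for both isotopologues when rates are expressed as mass of CH4.
.const <- list(
  molar_mass_ch4 = 16.04,   # g/mol
  molar_mass_13c = 13.003,  # g/mol, isotopic mass of 13C
  molar_mass_c   = 12.011,  # g/mol, standard atomic weight of carbon
  vm_stp         = 22.414,  # L/mol at 0 degC, 1 atm
  t_zero         = 273.15   # K at 0 degC
)

#' Ideal-gas molar volume
#'
#' Molar volume of an ideal gas at the given temperature and pressure.
#'
#' @param temperature Temperature in degrees Celsius.
#' @param pressure Total pressure in atm.
#' @return Molar volume in liters per mole (24.055 L/mol at 20 degC, 1 atm).
#' @export
molar_volume <- function(temperature, pressure = 1) {
  stopifnot(is.finite(temperature), is.finite(pressure), pressure > 0)
  if (any(temperature <= -.const$t_zero)) {
    stop("temperature must be above absolute zero (-273.15 degC)")
  }
  .const$vm_stp * ((temperature + .const$t_zero) / .const$t_zero) / pressure
}

#' Convert a headspace mixing ratio to mass of CH4
#'
#' Converts a CH4 mixing ratio (ppmv) in a closed headspace of known volume,
#' temperature and pressure to nanograms of CH4, assuming ideal-gas behaviour
#' and a molar mass of 16.04 g/mol.
#'
#' @param mixing_ratio CH4 mixing ratio in ppmv.
#' @param volume Headspace volume in liters.
#' @param temperature Temperature in degrees Celsius.
#' @param pressure Total pressure in atm.
#' @return Mass of CH4 in nanograms.
#' @examples
#' ppm_to_mass(500, 0.105, 20, 1)  # ~35,000 ng in a 125-ml bottle headspace
#' @export
ppm_to_mass <- function(mixing_ratio, volume, temperature = 20, pressure = 1) {
  stopifnot(all(is.finite(mixing_ratio)), mixing_ratio >= 0,
            volume >= 0, pressure >= 0)
  mol <- mixing_ratio * 1e-6 * volume / molar_volume(temperature, pressure)
  mol * .const$molar_mass_ch4 * 1e9
}

#' Convert a mass of CH4 to a headspace mixing ratio
#'
#' Inverse of [ppm_to_mass()].
#'
#' @param mass_ng Mass of CH4 in nanograms.
#' @inheritParams ppm_to_mass
#' @return Mixing ratio in ppmv.
#' @export
mass_to_ppm <- function(mass_ng, volume, temperature = 20, pressure = 1) {
  stopifnot(all(is.finite(mass_ng)), mass_ng >= 0, volume > 0)
  mol <- mass_ng * 1e-9 / .const$molar_mass_ch4
  mol / (volume / molar_volume(temperature, pressure)) * 1e6
}

#' Headspace mixing ratio to dissolved (aqueous) concentration
#'
#' Converts a CH4 headspace mixing ratio to the equilibrium dissolved
#' concentration in the sediment pore water using the Bunsen solubility
#' coefficient: `beta * (ppm * 1e-6 * pressure) / Vm(T)`, with the molar
#' volume evaluated at the incubation temperature (24.055 L/mol at 20 degC),
#' not at STP.
#'
#' @param mixing_ratio CH4 mixing ratio in ppmv.
#' @param temperature Temperature in degrees Celsius.
#' @param pressure Total pressure in atm.
#' @param bunsen Bunsen solubility coefficient (dimensionless; 0.034 for CH4
#'   at 20 degC).
#' @return Dissolved CH4 concentration in nM.
#' @examples
#' headspace_to_aqueous(138.8, 20, 1, 0.034)  # ~196 nM
#' @export
headspace_to_aqueous <- function(mixing_ratio, temperature = 20, pressure = 1,
                                 bunsen = 0.034) {
  stopifnot(all(is.finite(mixing_ratio)), all(mixing_ratio >= 0),
            is.finite(pressure), pressure >= 0, is.finite(bunsen), bunsen >= 0)
  partial_atm <- mixing_ratio * 1e-6 * pressure
  mol_per_l <- bunsen * partial_atm / molar_volume(temperature, 1)
  mol_per_l * 1e9
}

#' Dissolved concentration back to headspace mixing ratio
#'
#' Inverse of [headspace_to_aqueous()]; mainly used for consistency checks.
#'
#' @param conc_nm Dissolved CH4 concentration in nM.
#' @inheritParams headspace_to_aqueous
#' @return Mixing ratio in ppmv.
#' @export
aqueous_to_headspace <- function(conc_nm, temperature = 20, pressure = 1,
                                 bunsen = 0.034) {
  stopifnot(all(is.finite(conc_nm)), all(conc_nm >= 0), bunsen > 0, pressure > 0)
  conc_nm * 1e-9 * molar_volume(temperature, 1) / (bunsen * pressure * 1e-6)
}
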