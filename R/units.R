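## Unit conventions used throughout the package:
##   - all internal lengths are micrometres (um)
##   - energies in keV, wavelengths in Angstrom at the API boundary
##   - sample-to-detector distances in cm at the API boundary
##   - spatial frequencies in cycles per um

#' Planck constant times speed of light, keV * Angstrom
#'
#' Used to convert photon energy to wavelength, lambda = hc / E.
#' @keywords internal
HC_KEV_ANGSTROM <- 12.39842

#' Convert photon energy to wavelength
#'
#' @param energy_kev photon energy in keV (> 0)
#' @return wavelength in Angstrom
#' @examples
#' energy_to_wavelength(22)  # ~0.5636 Angstrom
#' @export
energy_to_wavelength <- function(energy_kev) {
  stopifnot(is.numeric(energy_kev), all(energy_kev > 0))
  HC_KEV_ANGSTROM / energy_kev
}

#' @keywords internal
angstrom_to_um <- function(x) x * 1e-4

#' @keywords internal
cm_to_um <- function(x) x * 1e4

#' Linear attenuation coefficient from the absorption index
#'
#' mu = 4 * pi * beta / lambda.
#'
#' @param beta unitless absorption index
#' @param wavelength_A wavelength in Angstrom
#' @return mu in 1/um
#' @export
beta_to_mu <- function(beta, wavelength_A) {
  4 * pi * beta / angstrom_to_um(wavelength_A)
}

#' Absorption index from the linear attenuation coefficient
#'
#' @param mu_per_um linear attenuation coefficient in 1/um
#' @param wavelength_A wavelength in Angstrom
#' @return unitless beta
#' @export
mu_to_beta <- function(mu_per_um, wavelength_A) {
  mu_per_um * angstrom_to_um(wavelength_A) / (4 * pi)
}
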