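#' X-ray beam description
#'
#' A monochromatic, fully coherent parallel beam. The wavelength is derived
#' from the energy (lambda = hc/E, hc = 12.39842 keV*Angstrom). The photon
#' budget drives the Poisson detector-noise model: when `photons_per_pixel`
#' is finite, each detected pixel value I is replaced by
#' Poisson(N * I) / N with N = `photons_per_pixel`.
#'
#' @param energy_kev photon energy in keV; default 22 (synchrotron lung
#'   imaging energy used throughout the package defaults)
#' @param photons_per_pixel expected photon count per detector pixel in the
#'   flat field, or `Inf` to disable noise. Default 5000 (relative noise
#'   ~1.4%, a typical per-projection fluence for synchrotron microCT).
#' @return an object of class `beam_spec` with fields `energy_kev`,
#'   `wavelength_A`, `photons_per_pixel`
#' @export
beam_spec <- function(energy_kev = 22, photons_per_pixel = 5000) {
  stopifnot(is.numeric(energy_kev), length(energy_kev) == 1, energy_kev > 0)
  stopifnot(is.numeric(photons_per_pixel), length(photons_per_pixel) == 1,
            photons_per_pixel > 0)
  structure(
    list(
      energy_kev = energy_kev,
      wavelength_A = energy_to_wavelength(energy_kev),
      photons_per_pixel = photons_per_pixel
    ),
    class = "beam_spec"
  )
}

#' @export
print.beam_spec <- function(x, ...) {
  cat(sprintf("<beam_spec> E = %g keV (lambda = %.5f A), photons/pixel = %g\n",
              x$energy_kev, x$wavelength_A, x$photons_per_pixel))
  invisible(x)
}
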