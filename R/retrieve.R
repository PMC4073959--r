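#' Parameters of the single-distance TIE phase-retrieval filter
#'
#' The retrieval assumes a homogeneous object with a constant delta/beta
#' ratio `gamma` (1950 for lung soft tissue at 22 keV; ~250 for bone).
#'
#' @param gamma delta/beta ratio (> 0); `gamma = 0` is accepted and makes
#'   the filter the identity (pure absorption processing)
#' @param distance_cm sample-to-detector distance R in cm (>= 0)
#' @param energy_kev photon energy in keV
#' @param pixel_size_um detector pixel in um
#' @param padding pad margin policy in px (each side, before rounding the
#'   padded size up to a power of two); matches the simulator default
#' @return object of class `retrieval_params`
#' @export
retrieval_params <- function(gamma = 1950, distance_cm = 30,
                             energy_kev = 22, pixel_size_um = 9,
                             padding = 64L) {
  stopifnot(gamma >= 0, distance_cm >= 0, energy_kev > 0, pixel_size_um > 0)
  structure(
    list(gamma = gamma, distance_cm = distance_cm,
         energy_kev = energy_kev,
         wavelength_A = energy_to_wavelength(energy_kev),
         pixel_size_um = pixel_size_um, padding = as.integer(padding)),
    class = "retrieval_params"
  )
}

#' @export
print.retrieval_params <- function(x, ...) {
  cat(sprintf(
    "<retrieval_params> gamma = %g, R = %g cm, E = %g keV, px = %g um\n",
    x$gamma, x$distance_cm, x$energy_kev, x$pixel_size_um))
  invisible(x)
}

#' TIE (Paganin-type) low-pass filter gain
#'
#' G(f) = 1 / (1 + pi * lambda * R * gamma * |f|^2), with f in cycles/um
#' and all lengths converted to um internally. G(0) = 1; G is strictly
#' decreasing in |f|; G is identically 1 when gamma = 0 or R = 0.
#'
#' @param f spatial frequency magnitude in cycles/um (vector ok)
#' @param params a `retrieval_params`
#' @return unitless gain in (0, 1]
#' @export
tie_filter_gain <- function(f, params) {
  stopifnot(inherits(params, "retrieval_params"))
  lam <- angstrom_to_um(params$wavelength_A)
  R <- cm_to_um(params$distance_cm)
  1 / (1 + pi * lam * R * params$gamma * f^2)
}

#' Single-distance TIE phase retrieval of one projection
#'
#' A(x, y) = -ln( IFFT[ FFT[I] * G(f) ] ) with G from [tie_filter_gain()]
#' and I flat-field normalized (I0 = 1 by convention). The image is
#' reflect-padded before the FFT (same policy as the simulator) and
#' cropped afterwards. For gamma = 0 this reduces exactly to -ln(I).
#'
#' @param intensity numeric matrix, > 0 everywhere
#' @param params a `retrieval_params`
#' @return retrieved projected attenuation A = mu * T (unitless), same shape
#' @export
retrieve_projection <- function(intensity, params) {
  stopifnot(is.matrix(intensity), inherits(params, "retrieval_params"))
  if (any(intensity <= 0))
    stop("intensity must be > 0 everywhere (flat-field normalized)")
  if (params$gamma == 0 || params$distance_cm == 0)
    return(-log(intensity))
  nr <- nrow(intensity); nc <- ncol(intensity)
  p <- pad_reflect(intensity, padded_dim(nr, params$padding),
                   padded_dim(nc, params$padding))
  fy <- fft_freq(nrow(p$m), params$pixel_size_um)
  fx <- fft_freq(ncol(p$m), params$pixel_size_um)
  G <- 1 / (1 + pi * angstrom_to_um(params$wavelength_A) *
              cm_to_um(params$distance_cm) * params$gamma *
              outer(fy^2, fx^2, "+"))
  sm <- Re(ifft2(fft2(p$m) * G))
  sm <- sm[p$top + seq_len(nr), p$left + seq_len(nc)]
  if (any(sm <= 0))
    stop("filtered intensity non-positive; retrieval log undefined")
  A <- -log(sm)
  if (any(!is.finite(A))) stop("NaN/Inf in retrieved projection")
  A
}

#' Stack of phase-retrieved projections
#'
#' @param images 3D array (angle, row, column) of retrieved projected
#'   attenuation
#' @param source a `projection_stack` the geometry is copied from
#' @param params the `retrieval_params` used
#' @return object of class `retrieved_stack`
#' @export
retrieved_stack <- function(images, source, params) {
  stopifnot(identical(dim(images), dim(source$intensities)),
            all(is.finite(images)))
  structure(
    list(images = images, angles = source$angles,
         distance_cm = source$distance_cm,
         pixel_size_um = source$pixel_size_um, beam = source$beam,
         params = params),
    class = "retrieved_stack"
  )
}

#' @export
print.retrieved_stack <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf(
    "<retrieved_stack> %d angles x %d x %d px, R = %g cm, gamma = %g\n",
    d[1], d[2], d[3], x$distance_cm, x$params$gamma))
  invisible(x)
}

#' Phase-retrieve every projection of a stack
#'
#' Applies [retrieve_projection()] per angle. The stack geometry (distance,
#' energy, pixel size) must match `params` unless `override = TRUE`.
#'
#' @param stack a `projection_stack`
#' @param params a `retrieval_params`
#' @param override allow a deliberate geometry mismatch
#' @return a `retrieved_stack`
#' @export
retrieve_stack <- function(stack, params, override = FALSE) {
  stopifnot(inherits(stack, "projection_stack"),
            inherits(params, "retrieval_params"))
  if (!override) {
    mismatch <- c(
      if (!isTRUE(all.equal(stack$distance_cm, params$distance_cm)))
        "distance",
      if (!isTRUE(all.equal(stack$beam$energy_kev, params$energy_kev)))
        "energy",
      if (!isTRUE(all.equal(stack$pixel_size_um, params$pixel_size_um)))
        "pixel size")
    if (length(mismatch))
      stop("stack/params geometry mismatch (", paste(mismatch, collapse = ", "),
           "); pass override = TRUE to force")
  }
  d <- dim(stack$intensities)
  A <- array(0, dim = d)
  for (a in seq_len(d[1]))
    A[a, , ] <- retrieve_projection(stack$intensities[a, , ], params)
  retrieved_stack(A, stack, params)
}

#' Convert a reconstructed attenuation map to a delta map
#'
#' delta = gamma * beta = gamma * mu * lambda / (4 pi), voxelwise.
#'
#' @param recon_mu numeric array of mu values in 1/um
#' @param gamma delta/beta ratio (> 0)
#' @param wavelength_A wavelength in Angstrom
#' @return array of delta values, same shape
#' @export
attenuation_to_delta <- function(recon_mu, gamma, wavelength_A) {
  if (gamma <= 0) stop("gamma must be positive")
  gamma * mu_to_beta(recon_mu, wavelength_A)
}
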