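## Forward model: parallel, monochromatic, fully coherent beam along the
## column axis of the volume; projection by in-plane rotation of the voxel
## grid (bilinear interpolation) and summation; free-space propagation by
## the angular-spectrum method with transfer function
## H(f) = exp(-i * pi * lambda * R * |f|^2), f in cycles per unit length.

## Bilinear gather weights for rotating an (nr x nc) in-plane grid by
## `angle` degrees about its center. Returns flattened source indices and
## weights; out-of-field samples get weight 0.
rotation_weights <- function(nr, nc, angle_deg) {
  th <- angle_deg * pi / 180
  cs <- cos(th); sn <- sin(th)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  gr <- rep(seq_len(nr) - cr, times = nc)
  gc <- rep(seq_len(nc) - cc, each = nr)
  sr <- cs * gr - sn * gc + cr
  sc <- sn * gr + cs * gc + cc
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  w00 <- (1 - fr) * (1 - fc); w01 <- (1 - fr) * fc
  w10 <- fr * (1 - fc); w11 <- fr * fc
  clampi <- function(r, c, w) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    w[!ok] <- 0
    idx <- pmin(pmax(r, 1L), nr) + (pmin(pmax(c, 1L), nc) - 1L) * nr
    list(idx = idx, w = w)
  }
  list(clampi(r0, c0, w00), clampi(r0, c0 + 1, w01),
       clampi(r0 + 1, c0, w10), clampi(r0 + 1, c0 + 1, w11))
}

#' Line integrals of a scalar voxel field along the beam direction
#'
#' Rotates the volume in-plane by `angle_deg` and sums along the column
#' axis. Returns a (slice x row) matrix of integrals in units of
#' `field * um`.
#'
#' @param field 3D array (slice, row, column)
#' @param angle_deg projection angle in degrees
#' @param voxel_size voxel edge in um
#' @param weights optional precomputed [rotation_weights()] result
#' @return matrix (n_slice x n_row): detector row = volume slice, detector
#'   column = volume row axis
#' @keywords internal
project_field <- function(field, angle_deg, voxel_size, weights = NULL) {
  d <- dim(field)
  nz <- d[1]; nr <- d[2]; nc <- d[3]
  if (is.null(weights)) weights <- rotation_weights(nr, nc, angle_deg)
  vm <- matrix(field, nz, nr * nc)
  acc <- matrix(0, nz, nr * nc)
  for (wq in weights) {
    nzw <- wq$w != 0
    if (!any(nzw)) next
    acc <- acc + vm[, wq$idx, drop = FALSE] *
      matrix(wq$w, nz, nr * nc, byrow = TRUE)
  }
  dim(acc) <- c(nz, nr, nc)
  rowSums(acc, dims = 2) * voxel_size
}

#' Complex transmission function of a volume at one view angle
#'
#' t(x, y) = exp(-(2 pi / lambda) integral beta dz) *
#'           exp(-i (2 pi / lambda) integral delta dz),
#' line integrals taken along the rotated beam direction. |t| <= 1.
#'
#' @param volume a `complex_index_volume`
#' @param angle_deg view angle in degrees, in [0, 360)
#' @param beam a `beam_spec`
#' @return complex matrix (detector row x detector column)
#' @export
complex_transmission <- function(volume, angle_deg, beam) {
  stopifnot(inherits(volume, "complex_index_volume"),
            inherits(beam, "beam_spec"))
  if (angle_deg < 0 || angle_deg >= 360) stop("angle must be in [0, 360)")
  lam_um <- angstrom_to_um(beam$wavelength_A)
  w <- rotation_weights(dim(volume$delta)[2], dim(volume$delta)[3], angle_deg)
  ## one complex-valued projection pass carries both line integrals
  pc <- (2 * pi / lam_um) * project_field(volume$beta + 1i * volume$delta,
                                          angle_deg, volume$voxel_size, w)
  pb <- Re(pc); pd <- Im(pc)
  if (any(pb < -1e-12 * max(abs(pb), 1)))
    stop("negative projected absorption implies |t| > 1 (negative beta?)")
  exp(-pb) * exp(-1i * pd)
}

## symmetric (edge-repeating) reflection of out-of-range indices into 1..n
reflect_index <- function(p, n) {
  m <- (p - 1) %% (2 * n)
  ifelse(m < n, m + 1, 2 * n - m)
}

## reflect (symmetric) padding of a matrix to target dims, centered;
## margins larger than the image fold back repeatedly
pad_reflect <- function(m, nr_t, nc_t) {
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(nr_t >= nr, nc_t >= nc)
  top <- (nr_t - nr) %/% 2; left <- (nc_t - nc) %/% 2
  ridx <- reflect_index(seq_len(nr_t) - top, nr)
  cidx <- reflect_index(seq_len(nc_t) - left, nc)
  list(m = m[ridx, cidx, drop = FALSE], top = top, left = left)
}

next_pow2 <- function(n) 2^ceiling(log2(n))

## padded dims used by both the propagator and the retrieval filter so that
## retrieval inverts simulation under one convention: next power of two
## with at least 64 px margin per side
padded_dim <- function(n, margin = 64L) next_pow2(n + 2L * margin)

## FFT frequency grid in cycles per um for n samples at pitch `pitch_um`
fft_freq <- function(n, pitch_um) {
  k <- seq_len(n) - 1L
  k[k >= n / 2] <- k[k >= n / 2] - n
  k / (n * pitch_um)
}

fft2 <- function(m) stats::fft(m)
ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

#' Fresnel free-space propagation (angular spectrum)
#'
#' Applies the paraxial transfer function
#' H(f) = exp(-i pi lambda R |f|^2) in the Fourier domain. The propagator
#' is unitary (energy conserving); R = 0 returns the input unchanged.
#' With `pad = TRUE` (default) the field is reflect-padded to the next
#' power of two with >= 64 px margin and cropped afterwards to suppress
#' periodic-boundary fringes.
#'
#' A warning is issued when the width of the first Fresnel fringe
#' sqrt(lambda R) falls below one pixel: the detector then undersamples the
#' finest interference fringes (true of the default 9 um / 22 keV geometry
#' at all three standard distances, as in real acquisitions).
#'
#' @param field complex (or numeric) matrix
#' @param distance_cm propagation distance R in cm (>= 0)
#' @param wavelength_A wavelength in Angstrom
#' @param pixel_size_um pixel pitch in um
#' @param pad logical, reflect-pad before the FFT (default TRUE)
#' @param warn_sampling logical, emit the fringe-sampling warning
#' @return complex matrix, same shape as input
#' @export
fresnel_propagate <- function(field, distance_cm, wavelength_A,
                              pixel_size_um, pad = TRUE,
                              warn_sampling = TRUE) {
  stopifnot(is.matrix(field), distance_cm >= 0)
  if (distance_cm == 0) return(field)
  lam <- angstrom_to_um(wavelength_A)
  R <- cm_to_um(distance_cm)
  if (warn_sampling && sqrt(lam * R) < pixel_size_um)
    warning(sprintf(paste0("first Fresnel fringe (%.2f um) narrower than ",
                           "one pixel (%g um): finest fringes are ",
                           "undersampled"), sqrt(lam * R), pixel_size_um))
  nr <- nrow(field); nc <- ncol(field)
  if (pad) {
    p <- pad_reflect(field, padded_dim(nr), padded_dim(nc))
    fpad <- p$m
  } else {
    fpad <- field
  }
  fy <- fft_freq(nrow(fpad), pixel_size_um)
  fx <- fft_freq(ncol(fpad), pixel_size_um)
  H <- exp(-1i * pi * lam * R * outer(fy^2, fx^2, "+"))
  out <- ifft2(fft2(fpad) * H)
  if (pad) out <- out[p$top + seq_len(nr), p$left + seq_len(nc)]
  out
}

#' Detector model: intensity plus optional Poisson noise
#'
#' I = |field|^2; with noise enabled, each pixel is replaced by
#' Poisson(N * I) / N where N = `beam$photons_per_pixel`. Zero-count pixels
#' are clamped to 0.5/N so flat-field-normalized intensities stay strictly
#' positive (the downstream log requires it). Deterministic under `seed`.
#'
#' @param field complex (or numeric) matrix
#' @param beam a `beam_spec`
#' @param seed integer seed for the noise draw (required when noise is on)
#' @param noise logical; defaults to TRUE when the photon budget is finite
#' @return numeric intensity matrix
#' @export
detect <- function(field, beam, seed = NULL,
                   noise = is.finite(beam$photons_per_pixel)) {
  I <- Mod(field)^2
  if (!noise) return(I)
  if (!is.finite(beam$photons_per_pixel))
    stop("photons_per_pixel must be finite when noise is enabled")
  if (is.null(seed)) stop("seed required for the Poisson noise draw")
  N <- beam$photons_per_pixel
  counts <- local_seed(seed, stats::rpois(length(I), N * as.vector(I)))
  matrix(pmax(counts, 0.5) / N, nrow(I), ncol(I))
}

#' Flat-field-normalized projection stack
#'
#' @param intensities 3D array (angle, row, column), > 0 everywhere
#' @param angles view angles in degrees, strictly increasing, span <= 360
#' @param distance_cm sample-to-detector distance in cm
#' @param pixel_size_um detector pixel in um
#' @param beam a `beam_spec`
#' @param noise_applied logical
#' @param seed integer or NULL
#' @return object of class `projection_stack`
#' @export
projection_stack <- function(intensities, angles, distance_cm,
                             pixel_size_um, beam, noise_applied = FALSE,
                             seed = NULL) {
  stopifnot(length(dim(intensities)) == 3,
            dim(intensities)[1] == length(angles))
  if (any(intensities <= 0)) stop("intensities must be > 0 (flat-fielded)")
  if (is.unsorted(angles, strictly = TRUE)) stop("angles must be increasing")
  if (diff(range(angles)) > 360) stop("angles must span <= 360 degrees")
  structure(
    list(intensities = intensities, angles = angles,
         distance_cm = distance_cm, pixel_size_um = pixel_size_um,
         beam = beam, noise_applied = noise_applied, seed = seed),
    class = "projection_stack"
  )
}

#' @export
print.projection_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<projection_stack> %d angles x %d x %d px @ %g um, R = %g cm, %s\n",
    d[1], d[2], d[3], x$pixel_size_um, x$distance_cm,
    if (x$noise_applied) "noisy" else "noise-free"))
  invisible(x)
}

## mean-bin a matrix by an integer factor in both dimensions
bin_matrix <- function(m, k) {
  if (k == 1L) return(m)
  nr <- nrow(m) %/% k; nc <- ncol(m) %/% k
  out <- matrix(0, nr, nc)
  for (i in seq_len(k)) for (j in seq_len(k))
    out <- out + m[seq(i, by = k, length.out = nr),
                   seq(j, by = k, length.out = nc)]
  out / k^2
}

#' Simulate an in-line phase-contrast CT scan
#'
#' Computes the complex transmission of the volume at `n_angles` evenly
#' spaced view angles over 360 degrees, Fresnel-propagates each projection
#' to every requested distance and applies the detector model. Per-distance
#' stacks share the same phantom and seed-derived noise streams.
#'
#' With `bin > 1` the intensity is mean-binned by that integer factor in
#' both detector dimensions before the noise draw: the volume is then a
#' supersampled rasterization and the detector integrates the intensity
#' over its pixel area, so sub-pixel interference fringes are averaged
#' rather than aliased (physically, a real pixel integrates; the reference
#' acquisition also binned 2x2). The recorded pixel size is
#' `voxel_size * bin` and `photons_per_pixel` refers to the binned pixel.
#'
#' @param volume a `complex_index_volume`
#' @param distances_cm numeric vector of sample-to-detector distances (cm)
#' @param n_angles number of projections over 360 degrees (>= 1)
#' @param beam a `beam_spec`
#' @param seed integer base seed for the noise streams
#' @param noise logical, apply Poisson detector noise
#' @param bin integer detector binning factor (default 1)
#' @return named list of `projection_stack`, one per distance
#' @export
simulate_scan <- function(volume, distances_cm, n_angles, beam,
                          seed = 1L, noise = is.finite(beam$photons_per_pixel),
                          bin = 1L) {
  stopifnot(n_angles >= 1, all(distances_cm >= 0), bin >= 1)
  angles <- seq(0, 360, length.out = n_angles + 1)[seq_len(n_angles)]
  ## opposing views of a full 360-degree scan are exact column mirrors
  ## (point reflection of the rotation plane about the grid center), and
  ## free-space propagation commutes with reflection (even kernel), so
  ## only the first half needs projecting and propagating
  fold <- n_angles %% 2L == 0L && n_angles >= 2L &&
    isTRUE(all.equal(diff(range(angles)), 360 * (n_angles - 1) / n_angles))
  n_base <- if (fold) n_angles %/% 2L else n_angles
  tlist <- vector("list", n_base)
  for (a in seq_len(n_base))
    tlist[[a]] <- complex_transmission(volume, angles[a], beam)
  bin <- as.integer(bin)
  nr <- nrow(tlist[[1]]) %/% bin; nc <- ncol(tlist[[1]]) %/% bin
  px_out <- volume$voxel_size * bin
  add_noise_px <- function(Ia, d, a) {
    if (!noise) return(Ia)
    N <- beam$photons_per_pixel
    cnts <- local_seed(seed + (d - 1L) * n_angles + (a - 1L),
                       stats::rpois(length(Ia), N * as.vector(Ia)))
    matrix(pmax(cnts, 0.5) / N, nr, nc)
  }
  out <- vector("list", length(distances_cm))
  names(out) <- paste0(distances_cm, "cm")
  for (d in seq_along(distances_cm)) {
    R <- distances_cm[d]
    lam <- angstrom_to_um(beam$wavelength_A)
    if (R > 0 && sqrt(lam * cm_to_um(R)) < px_out)
      warning(sprintf("distance %g cm: first Fresnel fringe narrower than one pixel", R))
    I <- array(0, dim = c(n_angles, nr, nc))
    for (a in seq_len(n_base)) {
      fR <- fresnel_propagate(tlist[[a]], R, beam$wavelength_A,
                              volume$voxel_size, warn_sampling = FALSE)
      Ia <- bin_matrix(Mod(fR)^2, bin)
      I[a, , ] <- add_noise_px(Ia, d, a)
      if (fold)
        I[a + n_base, , ] <- add_noise_px(Ia[, rev(seq_len(nc))],
                                          d, a + n_base)
    }
    out[[d]] <- projection_stack(I, angles, R, px_out, beam,
                                 noise_applied = noise,
                                 seed = if (noise) seed else NULL)
  }
  out
}

#' Add Poisson detector noise to a noise-free projection stack
#'
#' Convenience for reusing one noise-free simulation under several noise
#' settings; equivalent to having run [detect()] with noise enabled.
#'
#' @param stack a noise-free `projection_stack`
#' @param seed integer base seed
#' @param photons_per_pixel photon budget (defaults to the stack's beam)
#' @return a new `projection_stack` with `noise_applied = TRUE`
#' @export
apply_noise <- function(stack, seed,
                        photons_per_pixel = stack$beam$photons_per_pixel) {
  stopifnot(inherits(stack, "projection_stack"), !stack$noise_applied,
            is.finite(photons_per_pixel))
  N <- photons_per_pixel
  I <- stack$intensities
  counts <- local_seed(seed, stats::rpois(length(I), N * as.vector(I)))
  I2 <- array(pmax(counts, 0.5) / N, dim = dim(I))
  projection_stack(I2, stack$angles, stack$distance_cm, stack$pixel_size_um,
                   stack$beam, noise_applied = TRUE, seed = seed)
}

#' Write a projection stack to disk (raw float64 + JSON sidecar)
#'
#' @param stack a `projection_stack`
#' @param stem path stem
#' @return the sidecar path, invisibly
#' @export
write_stack <- function(stack, stem) {
  write_raw_array(stack$intensities, paste0(stem, ".raw"))
  side <- list(shape = dim(stack$intensities),
               angles_deg = stack$angles,
               distance_cm = stack$distance_cm,
               pixel_size_um = stack$pixel_size_um,
               energy_kev = stack$beam$energy_kev,
               photons_per_pixel = if (is.finite(stack$beam$photons_per_pixel))
                 stack$beam$photons_per_pixel else NULL,
               noise = stack$noise_applied,
               seed = stack$seed)
  path <- paste0(stem, ".json")
  jsonlite::write_json(side, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a projection stack written by [write_stack()]
#'
#' @param stem path stem used when writing
#' @return a `projection_stack`
#' @export
read_stack <- function(stem) {
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  I <- read_raw_array(paste0(stem, ".raw"), as.integer(side$shape))
  ppp <- side$photons_per_pixel
  if (is.null(ppp) || is.na(ppp)) ppp <- Inf
  projection_stack(I, side$angles_deg, side$distance_cm,
                   side$pixel_size_um,
                   beam_spec(side$energy_kev, ppp),
                   noise_applied = isTRUE(side$noise),
                   seed = side$seed)
}
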