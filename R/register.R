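## Registration protocol: the reference is the PBI volume at the smallest
## distance; moving volumes are matched slice-wise by zero-normalized 2D
## cross-correlation, then aligned in-plane by a Fourier-Mellin estimate
## of scale/rotation followed by phase-correlation translation recovery.
## PBI volumes are 3x3x3 mean-filtered for registration ONLY; all metric
## noise is measured on the original untransformed data.

#' 3x3x3 mean filter (registration pre-filter)
#'
#' Each voxel is replaced by the mean of its size^3 neighborhood with
#' reflected boundaries. Used only to drive registration of PBI volumes;
#' never for metric computation.
#'
#' @param volume 3D numeric array, >= 3 voxels per axis
#' @param size odd kernel edge length (default 3)
#' @return filtered array, same shape
#' @export
mean_filter_3d <- function(volume, size = 3L) {
  stopifnot(length(dim(volume)) == 3, all(dim(volume) >= 3),
            size %% 2 == 1, size >= 1)
  half <- (size - 1L) %/% 2L
  sm_axis <- function(x, axis) {
    n <- dim(x)[axis]
    acc <- array(0, dim(x))
    for (s in -half:half) {
      idx <- seq_len(n) + s
      idx[idx < 1] <- 1 - (idx[idx < 1] - 1) - 1   # reflect: 0 -> 1, -1 -> 2
      idx[idx > n] <- 2 * n - idx[idx > n] + 1
      acc <- acc + switch(axis, x[idx, , , drop = FALSE],
                          x[, idx, , drop = FALSE], x[, , idx, drop = FALSE])
    }
    acc / size
  }
  sm_axis(sm_axis(sm_axis(volume, 1L), 2L), 3L)
}

## zero-normalized correlation of two equally shaped matrices
zncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(0)
  sum(a * b) / den
}

#' Find the slice of a volume best matching a reference slice
#'
#' Maximizes zero-normalized 2D cross-correlation over slices; ties broken
#' by the lowest index.
#'
#' @param reference_slice 2D numeric matrix
#' @param moving_volume 3D array (slice, row, column), in-plane shape equal
#'   to the reference
#' @return list with `index` and `score`
#' @export
find_matching_slice <- function(reference_slice, moving_volume) {
  stopifnot(is.matrix(reference_slice), length(dim(moving_volume)) == 3)
  if (dim(moving_volume)[1] == 0) stop("empty moving volume")
  if (!all(dim(moving_volume)[2:3] == dim(reference_slice)))
    stop("in-plane shapes differ")
  scores <- vapply(seq_len(dim(moving_volume)[1]), function(k)
    zncc(reference_slice, moving_volume[k, , ]), numeric(1))
  k <- which.max(scores)          # which.max returns the first (lowest) max
  list(index = k, score = scores[k])
}

#' In-plane similarity transform
#'
#' Maps a moving image onto a fixed image: rotation about the image center
#' by `rotation_deg`, isotropic scaling by `scale`, then translation by
#' `translation` (row, column) pixels.
#'
#' @param scale unitless scale factor (> 0)
#' @param rotation_deg rotation in degrees
#' @param translation numeric length-2, (row, column) shift in pixels
#' @param score normalized correlation in [-1, 1] achieved after alignment
#' @param matched_slice_index slice index from [find_matching_slice()]
#' @return object of class `registration_transform`
#' @export
registration_transform <- function(scale = 1, rotation_deg = 0,
                                   translation = c(0, 0), score = NA_real_,
                                   matched_slice_index = NA_integer_) {
  stopifnot(scale > 0, length(translation) == 2)
  if (!is.na(score)) stopifnot(score >= -1 - 1e-9, score <= 1 + 1e-9)
  structure(list(scale = scale, rotation_deg = rotation_deg,
                 translation = as.numeric(translation), score = score,
                 matched_slice_index = matched_slice_index),
            class = "registration_transform")
}

#' @export
print.registration_transform <- function(x, ...) {
  cat(sprintf(
    "<registration_transform> scale %.4f, rot %.3f deg, shift (%.2f, %.2f) px, score %.3f\n",
    x$scale, x$rotation_deg, x$translation[1], x$translation[2], x$score))
  invisible(x)
}

## bilinear sampling of matrix `m` at (sr, sc); outside -> `fill`
bilinear_sample <- function(m, sr, sc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  val <- numeric(length(sr))
  inb <- r0 >= 1 & r0 + 1 <= nr & c0 >= 1 & c0 + 1 <= nc
  if (any(inb)) {
    r0i <- r0[inb]; c0i <- c0[inb]; fri <- fr[inb]; fci <- fc[inb]
    val[inb] <-
      m[cbind(r0i, c0i)] * (1 - fri) * (1 - fci) +
      m[cbind(r0i, c0i + 1)] * (1 - fri) * fci +
      m[cbind(r0i + 1, c0i)] * fri * (1 - fci) +
      m[cbind(r0i + 1, c0i + 1)] * fri * fci
  }
  val[!inb] <- fill
  attr(val, "mask") <- inb
  val
}

#' Apply a similarity transform to an image
#'
#' Resamples with bilinear interpolation. Out-of-field pixels are filled
#' with `fill` and flagged in the attached logical `mask` attribute
#' (TRUE = valid), so downstream metrics can exclude filled pixels.
#'
#' @param image numeric matrix
#' @param transform a `registration_transform`
#' @param fill fill value for out-of-field pixels
#' @return transformed matrix with a `mask` attribute
#' @export
apply_transform <- function(image, transform, fill = 0) {
  stopifnot(is.matrix(image), inherits(transform, "registration_transform"))
  nr <- nrow(image); nc <- ncol(image)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  th <- transform$rotation_deg * pi / 180
  cs <- cos(th); sn <- sin(th)
  gr <- rep(seq_len(nr), times = nc) - cr - transform$translation[1]
  gc <- rep(seq_len(nc), each = nr) - cc - transform$translation[2]
  ## invert: rotate by -th, scale by 1/s
  sr <- (cs * gr + sn * gc) / transform$scale + cr
  sc <- (-sn * gr + cs * gc) / transform$scale + cc
  v <- bilinear_sample(image, sr, sc, fill = fill)
  out <- matrix(v, nr, nc)
  attr(out, "mask") <- matrix(attr(v, "mask"), nr, nc)
  out
}

hann_window_2d <- function(nr, nc) {
  wr <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nr) - 1) / (nr - 1))
  wc <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nc) - 1) / (nc - 1))
  outer(wr, wc)
}

## fftshifted magnitude spectrum with Hann window and radial high-pass
## emphasis (suppresses the strong low-frequency content that would
## otherwise dominate the log-polar correlation)
log_magnitude_spectrum <- function(img) {
  w <- hann_window_2d(nrow(img), ncol(img))
  F <- fft2((img - mean(img)) * w)
  M <- Mod(F)
  nr <- nrow(M); nc <- ncol(M)
  M <- M[c((nr / 2 + 1):nr, 1:(nr / 2)), c((nc / 2 + 1):nc, 1:(nc / 2))]
  fy <- (seq_len(nr) - nr / 2 - 1) / nr
  fx <- (seq_len(nc) - nc / 2 - 1) / nc
  rad <- sqrt(outer(fy^2, fx^2, "+"))
  hp <- rad / max(rad)
  log1p(M) * hp
}

## resample an fftshifted spectrum onto a log-polar grid
## (n_theta angular samples over [0, pi), n_rad log-radial samples)
log_polar_resample <- function(M, n_theta = 360L, n_rad = 256L) {
  nr <- nrow(M); nc <- ncol(M)
  cr <- nr / 2 + 1; cc <- nc / 2 + 1
  r_max <- min(nr, nc) / 2 - 1
  r_min <- 1
  logstep <- log(r_max / r_min) / (n_rad - 1)
  radii <- r_min * exp((seq_len(n_rad) - 1) * logstep)
  thetas <- (seq_len(n_theta) - 1) * pi / n_theta
  sr <- cr + outer(sin(thetas), radii)
  sc <- cc + outer(cos(thetas), radii)
  v <- bilinear_sample(M, as.vector(sr), as.vector(sc), fill = 0)
  list(lp = matrix(v, n_theta, n_rad), logstep = logstep,
       theta_step_deg = 180 / n_theta)
}

## phase correlation peak between two equally shaped real matrices;
## returns the (row, col) shift of b relative to a with parabolic
## sub-pixel refinement and the normalized peak height
phase_correlation <- function(a, b) {
  Fa <- fft2(a); Fb <- fft2(b)
  cross <- Fa * Conj(Fb)
  mag <- Mod(cross)
  mag[mag < .Machine$double.eps] <- .Machine$double.eps
  r <- Re(ifft2(cross / mag))
  nr <- nrow(r); nc <- ncol(r)
  pk <- arrayInd(which.max(r), dim(r))
  subpix <- function(vm, v0, vp) {
    den <- vm - 2 * v0 + vp
    if (den == 0) 0 else max(-0.5, min(0.5, 0.5 * (vm - vp) / den))
  }
  ri <- pk[1]; ci <- pk[2]
  wrap <- function(i, n) ((i - 1) %% n) + 1
  dr <- subpix(r[wrap(ri - 1, nr), ci], r[ri, ci], r[wrap(ri + 1, nr), ci])
  dc <- subpix(r[ri, wrap(ci - 1, nc)], r[ri, ci], r[ri, wrap(ci + 1, nc)])
  sh_r <- ri - 1 + dr; sh_c <- ci - 1 + dc
  if (sh_r > nr / 2) sh_r <- sh_r - nr
  if (sh_c > nc / 2) sh_c <- sh_c - nc
  list(shift = c(sh_r, sh_c), peak = max(r))
}

#' Fourier-Mellin estimation of in-plane scale, rotation and translation
#'
#' Rotation and scale are recovered by phase correlation of the log-polar
#' resampled magnitude spectra (Hann-windowed, high-pass weighted); the
#' 180-degree rotation ambiguity inherent to the magnitude spectrum is
#' resolved by testing both candidates and keeping the higher-scoring one.
#' Translation is then recovered by a second phase correlation after
#' de-rotating/de-scaling the moving image. The returned transform maps
#' the moving image onto the fixed one (see [apply_transform()]).
#'
#' @param fixed,moving numeric matrices of identical shape
#' @param n_theta,n_rad log-polar grid size (default 360 x 256)
#' @param min_score final-correlation threshold below which the fit is
#'   flagged as non-converged (default 0.2; a warning, not an error)
#' @param refine logical: polish the log-polar estimate by a local
#'   correlation-maximizing search over rotation and scale (default TRUE;
#'   the raw estimate is accurate to about the angular bin width)
#' @return a `registration_transform`; attribute `converged` is FALSE when
#'   the final score fell below `min_score`
#' @export
fourier_mellin <- function(fixed, moving, n_theta = 360L, n_rad = 256L,
                           min_score = 0.2, refine = TRUE) {
  stopifnot(is.matrix(fixed), identical(dim(fixed), dim(moving)))
  Mf <- log_magnitude_spectrum(fixed)
  Mm <- log_magnitude_spectrum(moving)
  lpf <- log_polar_resample(Mf, n_theta, n_rad)
  lpm <- log_polar_resample(Mm, n_theta, n_rad)
  pc <- phase_correlation(lpf$lp, lpm$lp)
  ## the moving spectrum is the fixed one rotated by -rot and log-radially
  ## shifted by -log(scale): flip both correlation shifts
  rot <- -pc$shift[1] * lpf$theta_step_deg
  scl <- exp(-pc$shift[2] * lpf$logstep)
  candidates <- c(rot, rot + 180)
  best <- NULL
  for (cand in candidates) {
    tr <- registration_transform(scale = scl, rotation_deg = cand)
    ## applying the rotation/scale estimate aligns moving up to translation
    unrot <- apply_transform(moving, tr)
    w <- hann_window_2d(nrow(fixed), ncol(fixed))
    pct <- phase_correlation(fixed * w, unrot * w)
    tr$translation <- pct$shift
    aligned <- apply_transform(moving, tr)
    msk <- attr(aligned, "mask")
    sc <- zncc(fixed[msk], aligned[msk])
    if (is.null(best) || sc > best$score) {
      best <- tr
      best$score <- sc
    }
  }
  if (refine && best$score > 0) best <- fm_refine(fixed, moving, best)
  conv <- best$score >= min_score
  if (!conv)
    warning(sprintf("Fourier-Mellin score %.3f below threshold %.3f",
                    best$score, min_score))
  attr(best, "converged") <- conv
  best
}

## local polish of a Fourier-Mellin estimate: coordinate search over
## rotation and scale maximizing the aligned overlap correlation, with the
## translation re-estimated by phase correlation at each trial
fm_refine <- function(fixed, moving, tr0) {
  w <- hann_window_2d(nrow(fixed), ncol(fixed))
  eval_rs <- function(rot, scl) {
    cand <- registration_transform(scale = scl, rotation_deg = rot)
    unrot <- apply_transform(moving, cand)
    pct <- phase_correlation(fixed * w, unrot * w)
    cand$translation <- pct$shift
    aligned <- apply_transform(moving, cand)
    msk <- attr(aligned, "mask")
    cand$score <- zncc(fixed[msk], aligned[msk])
    cand
  }
  best <- tr0
  for (step in c(0.4, 0.1)) {
    for (dr in step * (-2:2)) {
      cand <- eval_rs(best$rotation_deg + dr, best$scale)
      if (cand$score > best$score) best <- cand
    }
    for (ds in 1 + step * 0.01 * (-2:2)) {
      cand <- eval_rs(best$rotation_deg, best$scale * ds)
      if (cand$score > best$score) best <- cand
    }
  }
  best$matched_slice_index <- tr0$matched_slice_index
  best
}

#' Register a moving reconstruction to a reference (paper protocol)
#'
#' Implements the full alignment protocol: PBI volumes are 3x3x3
#' mean-filtered for registration only; the matching slice is found by 2D
#' cross-correlation against the reference slice; scale/rotation/
#' translation then come from [fourier_mellin()]. The returned transform
#' carries the matched slice index. Metric noise must always be computed
#' from the untransformed volumes; this function never resamples the data
#' it is given.
#'
#' @param reference a `recon_volume` (by protocol: PBI at the smallest
#'   distance)
#' @param moving a `recon_volume` to align
#' @param reference_slice index of the reference slice (default: middle)
#' @return a `registration_transform`
#' @export
register_volumes <- function(reference, moving,
                             reference_slice = NULL) {
  stopifnot(inherits(reference, "recon_volume"),
            inherits(moving, "recon_volume"))
  ref_arr <- reference$slices
  mov_arr <- moving$slices
  ## volumes with fewer than 3 slices get the in-plane 3x3 mean only
  prefilter <- function(arr) {
    if (dim(arr)[1] >= 3) return(mean_filter_3d(arr))
    for (k in seq_len(dim(arr)[1]))
      arr[k, , ] <- mean_filter_3d(array(rep(arr[k, , ], 3),
                                         c(dim(arr)[2], dim(arr)[3], 3)),
                                   size = 3L)[, , 2]
    arr
  }
  if (reference$mode == "PBI") ref_arr <- prefilter(ref_arr)
  if (moving$mode == "PBI") mov_arr <- prefilter(mov_arr)
  if (is.null(reference_slice))
    reference_slice <- (dim(ref_arr)[1] + 1L) %/% 2L
  ref_sl <- ref_arr[reference_slice, , ]
  m <- find_matching_slice(ref_sl, mov_arr)
  tr <- fourier_mellin(ref_sl, mov_arr[m$index, , ])
  tr$matched_slice_index <- m$index
  tr
}

#' Serialize a registration transform to JSON
#' @param transform a `registration_transform`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(
    list(scale = transform$scale, rotation_deg = transform$rotation_deg,
         translation_px = transform$translation, score = transform$score,
         matched_slice = transform$matched_slice_index),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
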