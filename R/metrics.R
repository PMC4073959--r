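#' Rectangular ROI statistics
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) over a
#' rectangular ROI. Noise statistics entering CNR/EEI must come from
#' original, untransformed, unfiltered slices.
#'
#' @param slice numeric matrix
#' @param roi_rect integer length-4: (row, col, height, width), 1-based
#'   top-left corner plus extent, fully inside the slice
#' @param pixel_size_um pixel size in um
#' @param mask optional logical matrix (TRUE = valid); the ROI must not
#'   overlap invalid pixels
#' @return object of class `roi_stats`: mean, sd, n_pixels, area_mm2,
#'   roi_rect
#' @export
roi_stats <- function(slice, roi_rect, pixel_size_um, mask = NULL) {
  stopifnot(is.matrix(slice), length(roi_rect) == 4)
  r0 <- roi_rect[1]; c0 <- roi_rect[2]; h <- roi_rect[3]; w <- roi_rect[4]
  if (r0 < 1 || c0 < 1 || r0 + h - 1 > nrow(slice) ||
      c0 + w - 1 > ncol(slice))
    stop("ROI outside slice bounds")
  rows <- r0:(r0 + h - 1); cols <- c0:(c0 + w - 1)
  if (!is.null(mask) && !all(mask[rows, cols]))
    stop("ROI overlaps masked pixels")
  px <- slice[rows, cols]
  structure(list(mean = mean(px), sd = stats::sd(as.vector(px)),
                 n_pixels = length(px),
                 area_mm2 = length(px) * (pixel_size_um / 1000)^2,
                 roi_rect = roi_rect),
            class = "roi_stats")
}

#' Centered square ROI of a target area
#'
#' Chooses the square pixel count closest to `area_mm2` (e.g. the paper
#' protocol's 0.4 mm^2 at 9 um pixels gives ~4938 px, side 70).
#'
#' @param center length-2 (row, col) ROI center in pixels
#' @param area_mm2 target area in mm^2
#' @param pixel_size_um pixel size in um
#' @return integer length-4 roi_rect for [roi_stats()]
#' @export
roi_from_area <- function(center, area_mm2, pixel_size_um) {
  side <- max(1L, round(sqrt(area_mm2) / (pixel_size_um / 1000)))
  c(round(center[1] - side / 2 + 0.5), round(center[2] - side / 2 + 0.5),
    side, side)
}

#' Contrast-to-noise ratio between two tissues
#'
#' CNR = |mean_1 - mean_2| / sqrt((sd_1^2 + sd_2^2) / 2). Symmetric in its
#' arguments and invariant under joint affine intensity rescaling. The
#' alternative arithmetic-mean denominator (sd_1 + sd_2)/2 is available
#' via `denom = "mean"`.
#'
#' @param tissue,air `roi_stats` of the two adjoined tissues, measured on
#'   untransformed data
#' @param denom "rms" (default) or "mean"
#' @return unitless CNR; 0 when means are equal; +Inf (with a warning)
#'   when both sds are zero but means differ
#' @export
cnr <- function(tissue, air, denom = c("rms", "mean")) {
  denom <- match.arg(denom)
  dm <- abs(tissue$mean - air$mean)
  if (dm == 0) return(0)
  s <- switch(denom,
              rms = sqrt((tissue$sd^2 + air$sd^2) / 2),
              mean = (tissue$sd + air$sd) / 2)
  if (s == 0) {
    warning("zero noise with unequal means: CNR is infinite")
    return(Inf)
  }
  dm / s
}

#' Averaged line profile across an interface
#'
#' Samples `n_profiles` parallel segments at pixel pitch by bilinear
#' interpolation, offset perpendicular to the segment by `spacing_px`, and
#' returns their pointwise mean (the paper protocol: five 0.2 mm profiles
#' averaged).
#'
#' @param slice numeric matrix
#' @param segment_spec list with `start` and `end`, each (row, col) in
#'   pixel coordinates; sampled endpoint-inclusive at pixel pitch
#' @param n_profiles number of parallel profiles to average (default 5)
#' @param spacing_px perpendicular spacing between profiles (default 2)
#' @param pixel_size_um pixel size in um
#' @return object of class `line_profile`: `positions_mm` (uniform,
#'   strictly increasing), `values`, `n_averaged`, `length_mm`
#' @export
extract_profiles <- function(slice, segment_spec, n_profiles = 5,
                             spacing_px = 2, pixel_size_um = 9) {
  stopifnot(is.matrix(slice), !is.null(segment_spec$start),
            !is.null(segment_spec$end))
  p0 <- as.numeric(segment_spec$start); p1 <- as.numeric(segment_spec$end)
  len_px <- sqrt(sum((p1 - p0)^2))
  ns <- floor(len_px) + 1L
  tpar <- seq(0, 1, length.out = ns)
  dir <- (p1 - p0) / len_px
  perp <- c(-dir[2], dir[1])
  offs <- (seq_len(n_profiles) - (n_profiles + 1) / 2) * spacing_px
  acc <- numeric(ns)
  for (o in offs) {
    sr <- p0[1] + tpar * (p1[1] - p0[1]) + o * perp[1]
    sc <- p0[2] + tpar * (p1[2] - p0[2]) + o * perp[2]
    if (any(sr < 1 | sr > nrow(slice) | sc < 1 | sc > ncol(slice)))
      stop("profile segment exits slice bounds")
    acc <- acc + bilinear_sample(slice, sr, sc)
  }
  vals <- acc / n_profiles
  pos <- (seq_len(ns) - 1L) * pixel_size_um / 1000
  structure(list(positions_mm = pos, values = vals,
                 n_averaged = n_profiles,
                 length_mm = pos[ns] - pos[1]),
            class = "line_profile")
}

#' Noise estimate from profile end segments
#'
#' Standard deviations of the first and last `frac` of an edge profile
#' (the segments depicting pure air and pure tissue).
#'
#' @param profile a `line_profile`
#' @param frac fraction of samples per end segment (default 0.25)
#' @return list `sd_start`, `sd_end`
#' @export
profile_end_sds <- function(profile, frac = 0.25) {
  n <- length(profile$values)
  k <- max(2L, floor(frac * n))
  list(sd_start = stats::sd(profile$values[seq_len(k)]),
       sd_end = stats::sd(profile$values[(n - k + 1):n]))
}

#' Edge-enhancement index
#'
#' EEI = (P - L) / sqrt((sd_air^2 + sd_tissue^2)/2) with P and L the
#' highest and lowest values on the averaged profile. Invariant under
#' adding a constant to the profile. Zero for a flat profile.
#'
#' @param profile a `line_profile` crossing one air-tissue interface
#' @param sd_air,sd_tissue noise sds measured on original untransformed
#'   data (ROIs or profile end segments)
#' @param denom "rms" (default) or "mean", as in [cnr()]
#' @return unitless EEI
#' @export
eei <- function(profile, sd_air, sd_tissue, denom = c("rms", "mean")) {
  denom <- match.arg(denom)
  pl <- max(profile$values) - min(profile$values)
  if (pl == 0) return(0)
  s <- switch(denom,
              rms = sqrt((sd_air^2 + sd_tissue^2) / 2),
              mean = (sd_air + sd_tissue) / 2)
  if (s == 0) {
    warning("zero noise with non-flat profile: EEI is infinite")
    return(Inf)
  }
  pl / s
}

#' Sigmoid (logistic) edge fit
#'
#' Least-squares fit of f(x) = k1 + k4 / (1 + exp(-k2 (x - k3))) to an
#' averaged edge profile. k2 (1/mm) is the edge steepness. Descending
#' (tissue-to-air) profiles are mirrored before fitting so that k2 > 0;
#' the orientation is recorded and k3 is reported in the original
#' coordinates.
#'
#' @param profile a `line_profile` with >= 8 samples spanning an edge
#' @return object of class `sigmoid_fit`: k1 (baseline), k2 (steepness,
#'   1/mm), k3 (edge center, mm), k4 (amplitude), residual_rms,
#'   `converged` flag, `orientation` ("ascending"/"descending")
#' @export
fit_sigmoid <- function(profile) {
  x <- profile$positions_mm; y <- profile$values
  stopifnot(length(y) >= 8)
  if (diff(range(y)) <= 0) {
    return(structure(list(k1 = NA_real_, k2 = NA_real_, k3 = NA_real_,
                          k4 = NA_real_, residual_rms = NA_real_,
                          converged = FALSE, orientation = NA_character_),
                     class = "sigmoid_fit"))
  }
  n <- length(y)
  q <- max(2L, n %/% 4L)
  ascending <- mean(y[(n - q + 1):n]) >= mean(y[seq_len(q)])
  yy <- if (ascending) y else rev(y)
  rng <- diff(range(yy))
  k1_0 <- min(yy); k4_0 <- rng
  half <- k1_0 + rng / 2
  cross <- which(diff(sign(yy - half)) != 0)
  k3_0 <- if (length(cross)) x[cross[1]] else stats::median(x)
  slope <- max(abs(diff(yy)) / diff(x))
  k2_0 <- max(4 * slope / rng, 1 / diff(range(x)))
  f <- function(p) p[1] + p[4] / (1 + exp(-p[2] * (x - p[3])))
  sse <- function(p) sum((yy - f(p))^2)
  fit <- tryCatch({
    m <- stats::nls(yy ~ k1 + k4 / (1 + exp(-k2 * (x - k3))),
                    start = list(k1 = k1_0, k2 = k2_0, k3 = k3_0, k4 = k4_0),
                    algorithm = "port",
                    control = stats::nls.control(maxiter = 500,
                                                 warnOnly = FALSE))
    list(par = stats::coef(m)[c("k1", "k2", "k3", "k4")], ok = TRUE)
  }, error = function(e) NULL)
  if (is.null(fit)) {
    opt <- stats::optim(c(k1_0, k2_0, k3_0, k4_0), sse, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-12))
    fit <- list(par = opt$par, ok = opt$convergence == 0)
  }
  p <- as.numeric(fit$par)
  ## canonical sign: k2 > 0, k4 > 0 for the (mirrored-to-ascending) profile
  if (p[2] < 0) { p <- c(p[1] + p[4], -p[2], p[3], -p[4]) }
  res <- sqrt(mean((yy - f(p))^2))
  degenerate <- !all(is.finite(p)) || p[4] == 0
  k3_out <- if (ascending) p[3] else max(x) + min(x) - p[3]
  structure(list(k1 = p[1], k2 = p[2], k3 = k3_out, k4 = p[4],
                 residual_rms = res,
                 converged = isTRUE(fit$ok) && !degenerate,
                 orientation = if (ascending) "ascending" else "descending"),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "<sigmoid_fit> k1=%.4g k2=%.4g /mm k3=%.4g mm k4=%.4g rms=%.3g %s (%s)\n",
    x$k1, x$k2, x$k3, x$k4, x$residual_rms,
    if (x$converged) "converged" else "NOT converged", x$orientation))
  invisible(x)
}

#' Normalized steepness-of-fit table
#'
#' Expresses each fitted k2 as a percentage of the reference entry (the
#' paper sets the largest value, PBI 30 cm, to 100%). Unconverged fits are
#' reported as NA, not 0, mirroring the sigmoid-fit breakdown of PBI at
#' 100 cm.
#'
#' @param fits named list of `sigmoid_fit` (names like "PBI_30")
#' @param reference name of the reference entry; its fit must have
#'   converged
#' @return data.frame with columns `label`, `k2`, `steepness_percent`;
#'   the reference row is exactly 100
#' @export
steepness_percent <- function(fits, reference) {
  stopifnot(reference %in% names(fits))
  ref <- fits[[reference]]
  if (!isTRUE(ref$converged)) stop("reference fit did not converge")
  k2 <- vapply(fits, function(f)
    if (isTRUE(f$converged)) f$k2 else NA_real_, numeric(1))
  pct <- 100 * k2 / ref$k2
  pct[reference] <- 100
  data.frame(label = names(fits), k2 = unname(k2),
             steepness_percent = unname(pct), row.names = NULL)
}

## separable Gaussian smoothing with a 3-pixel kernel (reflect boundary)
gaussian3_smooth <- function(m, sigma = 0.8) {
  w <- stats::dnorm(-1:1, sd = sigma)
  w <- w / sum(w)
  sm <- function(x) {           # along rows of a matrix
    n <- nrow(x)
    x_m <- x[c(1, seq_len(n - 1)), , drop = FALSE]
    x_p <- x[c(seq_len(n - 1) + 1, n), , drop = FALSE]
    w[1] * x_m + w[2] * x + w[3] * x_p
  }
  t(sm(t(sm(m))))
}

#' Iterative Gaussian filtering of a PBI slice to a target edge steepness
#'
#' Repeatedly applies a fixed 3-pixel Gaussian kernel (sigma = 0.8 px) to
#' the slice, refitting the sigmoid after each pass, until the fitted k2
#' drops to `target_k2` (the paper's experiment: filter PBI until it
#' matches the PhR steepness, then compare CNR).
#'
#' @param pbi_slice numeric matrix (a PBI reconstruction)
#' @param target_k2 target steepness in 1/mm, at or below the slice's
#'   current fitted k2
#' @param profile_spec segment spec for [extract_profiles()]
#' @param roi_tissue,roi_air roi_rects for the achieved-CNR measurement
#' @param pixel_size_um pixel size in um
#' @param max_iter maximum smoothing passes (default 200)
#' @param sigma Gaussian sigma in px (default 0.8)
#' @return list: `slice` (filtered), `achieved_k2`, `achieved_cnr`,
#'   `passes`, `reached` (FALSE when target was unreachable), `k2_trace`
#' @export
match_steepness_by_gaussian <- function(pbi_slice, target_k2, profile_spec,
                                        roi_tissue, roi_air,
                                        pixel_size_um = 9, max_iter = 200,
                                        sigma = 0.8) {
  fit0 <- fit_sigmoid(extract_profiles(pbi_slice, profile_spec,
                                       pixel_size_um = pixel_size_um))
  if (fit0$converged && target_k2 > fit0$k2)
    stop("target_k2 exceeds the slice's current steepness")
  cur <- pbi_slice
  ## on strongly noise-dominated slices the unfiltered fit may not
  ## converge; the first smoothing passes restore it
  k2 <- if (fit0$converged) fit0$k2 else Inf
  trace <- if (fit0$converged) k2 else numeric(0)
  passes <- 0L
  while (k2 > target_k2 && passes < max_iter) {
    cur <- gaussian3_smooth(cur, sigma)
    passes <- passes + 1L
    ft <- fit_sigmoid(extract_profiles(cur, profile_spec,
                                       pixel_size_um = pixel_size_um))
    if (!ft$converged) next
    k2 <- ft$k2
    trace <- c(trace, k2)
  }
  reached <- k2 <= target_k2
  if (!reached)
    warning("target steepness not reached within max_iter passes")
  st_t <- roi_stats(cur, roi_tissue, pixel_size_um)
  st_a <- roi_stats(cur, roi_air, pixel_size_um)
  list(slice = cur, achieved_k2 = k2, achieved_cnr = cnr(st_t, st_a),
       passes = passes, reached = reached, k2_trace = trace)
}

#' Count curvature sign changes across an edge profile
#'
#' Overshoot-undershoot detector: counts sign changes of the second
#' difference of the profile, ignoring curvature excursions smaller than
#' `rel_threshold` of the profile range (diffraction fringes at an edge
#' are of the order of the edge step itself; gentle sample-texture
#' modulation is not). With `center`/`halfwidth` the count is restricted
#' to a window of samples around the interface, so plateau structure away
#' from the edge is not counted. A clean monotone edge gives 0-1; fringed
#' edges give >= 2.
#'
#' @param values numeric profile values
#' @param rel_threshold curvature magnitude threshold relative to the
#'   profile range (default 0.1)
#' @param center optional sample index of the interface
#' @param halfwidth window half-width in samples around `center`
#' @return integer count of sign changes
#' @export
curvature_sign_changes <- function(values, rel_threshold = 0.1,
                                   center = NULL, halfwidth = NULL) {
  amp <- diff(range(values))
  if (amp == 0) return(0L)
  if (!is.null(center)) {
    stopifnot(!is.null(halfwidth))
    lo <- max(1L, center - halfwidth)
    hi <- min(length(values), center + halfwidth)
    values <- values[lo:hi]
  }
  d2 <- diff(values, differences = 2)
  s <- sign(d2[abs(d2) > rel_threshold * amp])
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0)
}
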