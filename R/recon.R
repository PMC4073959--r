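#' Parallel-beam sinogram
#'
#' @param values matrix (angle x detector column)
#' @param angles view angles in degrees
#' @param pixel_size_um detector pixel in um
#' @return object of class `sinogram`
#' @export
sinogram <- function(values, angles, pixel_size_um) {
  stopifnot(is.matrix(values), nrow(values) == length(angles),
            all(is.finite(values)))
  structure(list(values = values, angles = angles,
                 pixel_size_um = pixel_size_um),
            class = "sinogram")
}

#' Sinogram formation from a projection or retrieved stack
#'
#' PBI mode applies -ln(I) to the raw intensities; PhR mode passes the
#' retrieved projected attenuation through unchanged. One sinogram per
#' detector row.
#'
#' @param stack a `projection_stack` (mode "PBI") or `retrieved_stack`
#'   (mode "PhR")
#' @param mode "PBI" or "PhR"; defaults to the natural mode of the input
#' @param rows detector rows to extract (default all)
#' @return list of `sinogram` objects, named by row index
#' @export
to_sinograms <- function(stack, mode = NULL, rows = NULL) {
  if (is.null(mode))
    mode <- if (inherits(stack, "retrieved_stack")) "PhR" else "PBI"
  mode <- match.arg(mode, c("PBI", "PhR"))
  if (mode == "PBI") {
    stopifnot(inherits(stack, "projection_stack"))
    if (any(stack$intensities <= 0))
      stop("non-positive intensity: -ln undefined in PBI mode")
    vals <- -log(stack$intensities)
  } else {
    stopifnot(inherits(stack, "retrieved_stack"))
    vals <- stack$images
  }
  d <- dim(vals)
  if (is.null(rows)) rows <- seq_len(d[2])
  out <- lapply(rows, function(r)
    sinogram(vals[, r, ], stack$angles, stack$pixel_size_um))
  names(out) <- as.character(rows)
  out
}

## frequency response of the band-limited ramp (Ram-Lak) kernel, sampled
## per Kak & Slaney so the DC term is handled correctly, plus optional
## smoothing window
ramp_response <- function(m, filter_name) {
  n <- c(0:(m / 2), (-m / 2 + 1):-1)
  h <- numeric(m)
  h[n == 0] <- 0.25
  odd <- n %% 2 != 0
  h[odd] <- -1 / (pi^2 * n[odd]^2)
  Hk <- Re(stats::fft(h))
  if (filter_name != "ramp") {
    fhat <- abs(fft_freq(m, 1)) / 0.5   # |f| / f_Nyquist in [0, 1]
    w <- switch(filter_name,
                "shepp-logan" = ifelse(fhat == 0, 1,
                                       sin(pi * fhat / 2) / (pi * fhat / 2)),
                "hann" = 0.5 * (1 + cos(pi * fhat)))
    Hk <- Hk * w
  }
  Hk
}

#' Filtered back-projection of one sinogram
#'
#' Standard parallel-beam FBP: band-limited ramp filtering (optionally
#' windowed) of each projection, then back-projection with linear
#' interpolation. Works for angle sets covering 180 or 360 degrees. The
#' output is scaled so that a uniform disk of linear attenuation mu
#' reconstructs to mu in 1/um (given sinogram values that are unitless
#' line integrals mu*T).
#'
#' @param sino a `sinogram`
#' @param filter_name "ramp" (default), "shepp-logan" or "hann"
#' @return square numeric matrix (n_det x n_det) of reconstructed values
#'   in 1/um
#' @export
fbp <- function(sino, filter_name = c("ramp", "shepp-logan", "hann")) {
  stopifnot(inherits(sino, "sinogram"))
  filter_name <- match.arg(filter_name)
  ang <- sino$angles
  if (length(ang) < 2) stop("need at least 2 angles")
  if (diff(range(ang)) == 0) stop("degenerate angle set (all equal)")
  P <- sino$values
  na <- nrow(P); nd <- ncol(P)
  m <- 2L * next_pow2(nd)
  Ppad <- matrix(0, na, m)
  Ppad[, seq_len(nd)] <- P
  Hk <- ramp_response(m, filter_name)
  ## filter all projections at once (columns of t(Ppad))
  F <- stats::mvfft(t(Ppad))
  Q <- Re(stats::mvfft(F * Hk, inverse = TRUE)) / m
  Q <- t(Q)[, seq_len(nd), drop = FALSE]   # (angle x detector), per-sample
  cen <- (nd + 1) / 2
  xs <- seq_len(nd) - cen
  DR <- rep(xs, times = nd)
  DC <- rep(xs, each = nd)
  acc <- numeric(nd * nd)
  th <- ang * pi / 180
  for (a in seq_len(na)) {
    t_det <- cos(th[a]) * DR + sin(th[a]) * DC + cen
    i0 <- floor(t_det)
    fr <- t_det - i0
    ok0 <- i0 >= 1 & i0 <= nd
    ok1 <- i0 + 1 >= 1 & i0 + 1 <= nd
    q <- Q[a, ]
    v <- numeric(nd * nd)
    v[ok0] <- v[ok0] + q[i0[ok0]] * (1 - fr[ok0])
    v[ok1] <- v[ok1] + q[i0[ok1] + 1] * fr[ok1]
    acc <- acc + v
  }
  matrix(acc * pi / na / sino$pixel_size_um, nd, nd)
}

#' Brute-force Radon transform (test oracle)
#'
#' Direct line-integral projection of a 2D image by coordinate rotation
#' and summation, independent of the main simulation path. Intended for
#' validating [fbp()] on small fixtures.
#'
#' @param image square numeric matrix
#' @param angles view angles in degrees
#' @return a `sinogram` with unit pixel size times the image's implied
#'   pitch of 1 (values are sums of pixel values, i.e. integrals with
#'   pitch 1)
#' @export
radon_oracle <- function(image, angles) {
  stopifnot(is.matrix(image), nrow(image) == ncol(image))
  n <- nrow(image)
  cen <- (n + 1) / 2
  out <- matrix(0, length(angles), n)
  for (k in seq_along(angles)) {
    th <- angles[k] * pi / 180
    cs <- cos(th); sn <- sin(th)
    for (j in seq_len(n)) {        # detector column (volume row offset)
      dy <- j - cen
      dx <- seq_len(n) - cen       # integration variable
      sr <- cs * dy - sn * dx + cen
      sc <- sn * dy + cs * dx + cen
      r0 <- floor(sr); c0 <- floor(sc)
      fr <- sr - r0; fc <- sc - c0
      s <- 0
      for (q in 1:4) {
        rr <- r0 + (q > 2)
        cc <- c0 + (q %% 2 == 0)
        w <- (if (q > 2) fr else 1 - fr) * (if (q %% 2 == 0) fc else 1 - fc)
        ok <- rr >= 1 & rr <= n & cc >= 1 & cc <= n
        if (any(ok))
          s <- s + sum(image[cbind(rr[ok], cc[ok])] * w[ok])
      }
      out[k, j] <- s
    }
  }
  sinogram(out, angles, 1)
}

#' Reconstructed CT volume
#'
#' @param slices 3D array (slice, row, column), square in-plane
#' @param pixel_size_um pixel in um
#' @param mode "PBI" or "PhR"
#' @param provenance list (distance_cm, gamma, filter, slice_rows, ...)
#' @return object of class `recon_volume`
#' @export
recon_volume <- function(slices, pixel_size_um, mode, provenance = list()) {
  stopifnot(length(dim(slices)) == 3, dim(slices)[2] == dim(slices)[3],
            all(is.finite(slices)))
  mode <- match.arg(mode, c("PBI", "PhR"))
  structure(list(slices = slices, pixel_size_um = pixel_size_um,
                 mode = mode, provenance = provenance),
            class = "recon_volume")
}

#' @export
print.recon_volume <- function(x, ...) {
  d <- dim(x$slices)
  cat(sprintf("<recon_volume:%s> %d slices of %d x %d px @ %g um, R = %s cm\n",
              x$mode, d[1], d[2], d[3], x$pixel_size_um,
              format(x$provenance$distance_cm %||% NA)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reconstruct selected detector rows of a stack into slices
#'
#' @param stack a `projection_stack` or `retrieved_stack`
#' @param rows detector row indices to reconstruct (default: central row)
#' @param mode "PBI"/"PhR" (defaults to the stack's natural mode)
#' @param filter_name FBP filter window
#' @return a `recon_volume`
#' @export
reconstruct_volume <- function(stack, rows = NULL, mode = NULL,
                               filter_name = "ramp") {
  d <- if (inherits(stack, "retrieved_stack")) dim(stack$images) else
    dim(stack$intensities)
  if (is.null(rows)) rows <- (d[2] + 1L) %/% 2L
  sinos <- to_sinograms(stack, mode = mode, rows = rows)
  mode <- if (inherits(stack, "retrieved_stack")) "PhR" else "PBI"
  sl <- array(0, dim = c(length(rows), d[3], d[3]))
  for (i in seq_along(sinos)) sl[i, , ] <- fbp(sinos[[i]], filter_name)
  gamma <- if (inherits(stack, "retrieved_stack")) stack$params$gamma else NA
  recon_volume(sl, stack$pixel_size_um, mode,
               provenance = list(distance_cm = stack$distance_cm,
                                 gamma = gamma, filter = filter_name,
                                 slice_rows = rows))
}

#' Write a reconstructed volume (raw float64 + JSON sidecar)
#' @param vol a `recon_volume`
#' @param stem path stem
#' @return the sidecar path, invisibly
#' @export
write_recon <- function(vol, stem) {
  write_raw_array(vol$slices, paste0(stem, ".raw"))
  side <- list(shape = dim(vol$slices), pixel_size_um = vol$pixel_size_um,
               mode = vol$mode, provenance = vol$provenance)
  path <- paste0(stem, ".json")
  jsonlite::write_json(side, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a reconstructed volume written by [write_recon()]
#' @param stem path stem used when writing
#' @return a `recon_volume`
#' @export
read_recon <- function(stem) {
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  sl <- read_raw_array(paste0(stem, ".raw"), as.integer(side$shape))
  recon_volume(sl, side$pixel_size_um, side$mode,
               provenance = as.list(side$provenance))
}

#' Grey-value histogram modality detector
#'
#' Builds a histogram, smooths the counts with a short running mean, finds
#' local maxima, and merges peaks that are not separated by a valley
#' falling below `separation` times the smaller peak. Reports the number
#' of separated modes and the valley-to-peak ratio of the two dominant
#' modes (1 when unimodal).
#'
#' @param values numeric vector of grey values
#' @param nbins number of histogram bins
#' @param smooth running-mean window (odd, in bins)
#' @param min_height peaks below this fraction of the tallest are ignored
#' @param separation valley/smaller-peak ratio below which two peaks count
#'   as separate modes
#' @return list with `n_modes`, `valley_to_peak`, `peak_positions`
#' @export
histogram_bimodality <- function(values, nbins = 64, smooth = 3,
                                 min_height = 0.1, separation = 0.5) {
  values <- values[is.finite(values)]
  h <- graphics::hist(values, breaks = nbins, plot = FALSE)
  cnt <- h$counts
  if (smooth > 1) {
    k <- rep(1 / smooth, smooth)
    cnt <- as.numeric(stats::filter(c(rep(cnt[1], smooth), cnt,
                                      rep(cnt[length(cnt)], smooth)),
                                    k, sides = 2))[smooth + seq_along(h$counts)]
  }
  n <- length(cnt)
  ispeak <- which(cnt >= c(-Inf, cnt[-n]) & cnt > c(cnt[-1], -Inf) &
                    cnt >= min_height * max(cnt))
  if (length(ispeak) == 0) ispeak <- which.max(cnt)
  ## merge peaks lacking a deep enough valley between them
  peaks <- ispeak[order(cnt[ispeak], decreasing = TRUE)]
  kept <- peaks[1]
  for (p in peaks[-1]) {
    sep_ok <- TRUE
    for (q in kept) {
      rng <- if (p < q) p:q else q:p
      valley <- min(cnt[rng])
      if (valley > separation * min(cnt[p], cnt[q])) { sep_ok <- FALSE; break }
    }
    if (sep_ok) kept <- c(kept, p)
  }
  kept <- sort(kept)
  if (length(kept) >= 2) {
    top2 <- kept[order(cnt[kept], decreasing = TRUE)][1:2]
    rng <- seq(min(top2), max(top2))
    vtp <- min(cnt[rng]) / min(cnt[top2])
  } else vtp <- 1
  list(n_modes = length(kept), valley_to_peak = vtp,
       peak_positions = h$mids[kept])
}
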