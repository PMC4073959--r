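test_that("roi_stats: constant, alternating and protocol-sized ROIs", {
  sl <- matrix(5, 40, 40)
  st <- roi_stats(sl, c(3, 3, 10, 10), 9)
  expect_equal(st$mean, 5)
  expect_equal(st$sd, 0)
  expect_equal(st$n_pixels, 100L)
  expect_equal(st$area_mm2, 100 * (9 / 1000)^2)
  alt <- matrix(c(0, 2), 40, 40)
  sa <- roi_stats(alt, c(1, 1, 40, 40), 9)
  expect_equal(sa$mean, 1)
  expect_equal(sa$sd, 1, tolerance = 1e-3)   # n-1 form, large n
  ## 0.4 mm^2 at 9 um -> ~4938 px (70 x 70 + remainder rounding)
  rect <- roi_from_area(c(100, 100), 0.4, 9)
  expect_equal(rect[3], 70)
  expect_equal(rect[3] * rect[4], 4900)
  expect_lt(abs(rect[3] * rect[4] - 0.4 / (0.009^2)), 70)
  expect_error(roi_stats(sl, c(38, 38, 10, 10), 9), "bounds")
  msk <- matrix(TRUE, 40, 40); msk[10, 10] <- FALSE
  expect_error(roi_stats(sl, c(8, 8, 5, 5), 9, mask = msk), "mask")
})

test_that("cnr: plug-in value, symmetry, edge cases, scale invariance", {
  st <- function(m, s) structure(list(mean = m, sd = s), class = "roi_stats")
  expect_equal(cnr(st(10, 1), st(0, 1)), 10)
  expect_equal(cnr(st(0, 1), st(10, 1)), 10)
  expect_equal(cnr(st(4, 2), st(4, 1)), 0)
  expect_warning(inf <- cnr(st(1, 0), st(0, 0)), "infinite")
  expect_identical(inf, Inf)
  expect_identical(cnr(st(3, 0), st(3, 0)), 0)
  c1 <- cnr(st(7, 2), st(1, 3))
  expect_equal(cnr(st(7 * 5, 2 * 5), st(1 * 5, 3 * 5)), c1)
  ## alternative denominator switch
  expect_equal(cnr(st(10, 1), st(0, 3), denom = "mean"), 10 / 2)
})

test_that("extract_profiles: sampling pitch, averaging, bounds", {
  sl <- matrix(2.5, 64, 64)
  seg <- list(start = c(32, 20), end = c(32, 42.222))  # 0.2 mm at 9 um
  pr <- extract_profiles(sl, seg, pixel_size_um = 9)
  expect_length(pr$values, 23L)          # floor(200/9) + 1
  expect_true(all(pr$values == 2.5))
  expect_equal(pr$length_mm, 22 * 0.009)
  expect_equal(diff(pr$positions_mm), rep(0.009, 22))
  ## averaging 5 identical profiles equals any single one
  grad <- matrix(rep(seq_len(64), each = 64) * 1.0, 64, 64)
  p5 <- extract_profiles(grad, seg, n_profiles = 5, spacing_px = 2,
                         pixel_size_um = 9)
  p1 <- extract_profiles(grad, seg, n_profiles = 1, pixel_size_um = 9)
  expect_equal(p5$values, p1$values, tolerance = 1e-12)
  expect_error(extract_profiles(sl, list(start = c(2, 60), end = c(2, 70))),
               "bounds")
})

test_that("eei: plug-in value and invariances", {
  pr <- sigmoid_profile(k1 = 0, k4 = 10, k2 = 80)
  expect_equal(eei(pr, 1, 1), (max(pr$values) - min(pr$values)) / 1)
  expect_equal(eei(pr, 1, 1), 10, tolerance = 0.01)
  flat <- sigmoid_profile(k4 = 0)
  expect_identical(eei(flat, 0, 0), 0)
  shifted <- pr; shifted$values <- pr$values + 100
  expect_equal(eei(shifted, 1, 1), eei(pr, 1, 1))
  expect_equal(eei(pr, 3, 1, denom = "mean"), 10 / 2, tolerance = 0.01)
})

test_that("profile_end_sds uses the outer quarters", {
  pr <- sigmoid_profile(n = 24)
  set.seed(1)
  pr$values <- pr$values + rnorm(24, sd = 0.01)
  sds <- profile_end_sds(pr)
  expect_equal(sds$sd_start, sd(pr$values[1:6]))
  expect_equal(sds$sd_end, sd(pr$values[19:24]))
})

test_that("sigmoid fit recovers exact parameters to 1e-6", {
  ft <- fit_sigmoid(sigmoid_profile(k1 = 0, k2 = 50, k3 = 0.1, k4 = 1))
  expect_true(ft$converged)
  expect_equal(ft$k2, 50, tolerance = 1e-6)
  expect_equal(ft$k3, 0.1, tolerance = 1e-6)
  expect_equal(ft$k4, 1, tolerance = 1e-6)
  expect_lt(ft$residual_rms, 1e-7)
  expect_identical(ft$orientation, "ascending")
})

test_that("sigmoid fit: k2 within 5% under 2% noise (100 seeded reps)", {
  k2s <- vapply(1:100, function(s)
    fit_sigmoid(sigmoid_profile(noise_sd = 0.02, seed = s))$k2, numeric(1))
  expect_lt(abs(mean(k2s) / 50 - 1), 0.05)
  expect_lt(abs(median(k2s) / 50 - 1), 0.05)
})

test_that("mirrored profiles fit with equal |k2| and recorded orientation", {
  pr <- sigmoid_profile(k2 = 40)
  mr <- pr; mr$values <- rev(pr$values)
  fa <- fit_sigmoid(pr); fd <- fit_sigmoid(mr)
  expect_identical(fd$orientation, "descending")
  expect_equal(fd$k2, fa$k2, tolerance = 1e-6)
  expect_gt(fd$k2, 0)
  ## degenerate flat profile is flagged, not an error
  flat <- sigmoid_profile(k4 = 0)
  expect_false(fit_sigmoid(flat)$converged)
})

test_that("steepness table normalizes to the reference fit", {
  mk <- function(k2, conv = TRUE)
    structure(list(k2 = k2, converged = conv), class = "sigmoid_fit")
  fits <- list(PBI_30 = mk(200), PhR_30 = mk(100), PBI_100 = mk(500, FALSE))
  tab <- steepness_percent(fits, "PBI_30")
  expect_equal(tab$steepness_percent[tab$label == "PBI_30"], 100)
  expect_equal(tab$steepness_percent[tab$label == "PhR_30"], 50)
  expect_true(is.na(tab$steepness_percent[tab$label == "PBI_100"]))
  expect_error(steepness_percent(fits, "PBI_100"), "converge")
})

test_that("gaussian steepness matching: zero-pass and monotone descent", {
  ## synthetic edge slice with a known steep edge along the columns
  n <- 64
  x <- (seq_len(n) - 1) * 9 / 1000
  sl <- matrix(rep(1 / (1 + exp(-300 * (x - x[32]))), each = n), n, n)
  seg <- list(start = c(32, 21), end = c(32, 43.222))
  roi_t <- c(5, 50, 10, 10); roi_a <- c(5, 5, 10, 10)
  cur <- fit_sigmoid(extract_profiles(sl, seg, pixel_size_um = 9))$k2
  same <- match_steepness_by_gaussian(sl, cur, seg, roi_t, roi_a)
  expect_identical(same$passes, 0L)
  expect_identical(same$slice, sl)
  res <- match_steepness_by_gaussian(sl, 0.6 * cur, seg, roi_t, roi_a)
  expect_true(res$reached)
  expect_lte(res$achieved_k2, 0.6 * cur)
  expect_true(all(diff(res$k2_trace) <= 1e-9))
  expect_error(match_steepness_by_gaussian(sl, 2 * cur, seg, roi_t, roi_a),
               "exceeds")
})

test_that("curvature counter separates fringed from monotone edges", {
  x <- seq(-1, 1, length.out = 41)
  mono <- tanh(4 * x)
  expect_lte(curvature_sign_changes(mono), 1L)
  fringed <- mono + 0.8 * exp(-((x - 0.15) / 0.06)^2) -
    0.8 * exp(-((x + 0.15) / 0.06)^2)
  expect_gte(curvature_sign_changes(fringed), 2L)
  expect_identical(curvature_sign_changes(rep(1, 30)), 0L)
})

test_that("CNR and EEI are invariant under joint affine rescaling", {
  set.seed(12)
  sl <- matrix(rnorm(64^2, 10, 2), 64, 64)
  roi1 <- c(4, 4, 12, 12); roi2 <- c(40, 40, 12, 12)
  seg <- list(start = c(32, 10), end = c(32, 32.222))
  base_cnr <- cnr(roi_stats(sl, roi1, 9), roi_stats(sl, roi2, 9))
  base_eei <- eei(extract_profiles(sl, seg, pixel_size_um = 9), 1, 2)
  sl2 <- 3.7 * sl + 11
  expect_equal(cnr(roi_stats(sl2, roi1, 9), roi_stats(sl2, roi2, 9)),
               base_cnr, tolerance = 1e-12)
  expect_equal(eei(extract_profiles(sl2, seg, pixel_size_um = 9),
                   3.7 * 1, 3.7 * 2), base_eei, tolerance = 1e-12)
})
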