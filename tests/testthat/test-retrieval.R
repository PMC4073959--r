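test_that("TIE filter gain matches the closed form and its limits", {
  p <- retrieval_params(gamma = 1950, distance_cm = 30, energy_kev = 22,
                        pixel_size_um = 9)
  ## independently computed oracle value (unit-conversion script):
  ## 1 / (1 + pi * 5.6356e-5 um * 3e5 um * 1950 * 1e-4 um^-2) = 0.08804857
  expect_equal(tie_filter_gain(0.01, p), 0.08804857, tolerance = 1e-7)
  expect_identical(tie_filter_gain(0, p), 1)
  expect_equal(tie_filter_gain(0.3, retrieval_params(distance_cm = 0)), 1)
  expect_equal(tie_filter_gain(0.3, retrieval_params(gamma = 0)), 1)
  f <- seq(0, 0.05, length.out = 50)
  expect_true(all(diff(tie_filter_gain(f, p)) < 0))
})

test_that("gain equals an in-test unit-conversion oracle at random f", {
  set.seed(99)
  fs <- runif(10, 1e-4, 0.055)
  p <- retrieval_params(gamma = 1950, distance_cm = 30, energy_kev = 22,
                        pixel_size_um = 9)
  ## oracle built in SI units, independently of the package's um pipeline
  lam_m <- (12.39842 / 22) * 1e-10
  R_m <- 0.30
  f_m <- fs * 1e6                       # cycles/m
  oracle <- 1 / (1 + pi * lam_m * R_m * 1950 * f_m^2)
  expect_equal(tie_filter_gain(fs, p), oracle, tolerance = 1e-12)
})

test_that("gamma = 0 retrieval reduces to -ln(I) at machine precision", {
  set.seed(3)
  I <- matrix(exp(rnorm(48 * 48, sd = 0.05)), 48, 48)
  p <- retrieval_params(gamma = 0, distance_cm = 30)
  expect_equal(retrieve_projection(I, p), -log(I), tolerance = 1e-12)
  expect_equal(retrieve_projection(matrix(1, 32, 32),
                                   retrieval_params(gamma = 1950)),
               matrix(0, 32, 32), tolerance = 1e-12)
  expect_error(retrieve_projection(matrix(c(-1, rep(1, 35)), 6, 6),
                                   retrieval_params()), "> 0")
})

test_that("DC gain 1 preserves the mean on the padded window", {
  vol <- make_edge_phantom(c(32L, 64L, 64L), delta_tissue = 4.06e-9)
  b <- tiny_beam()
  t0 <- complex_transmission(vol, 0, b)
  I30 <- Mod(fresnel_propagate(t0, 30, b$wavelength_A, 9,
                               warn_sampling = FALSE))^2
  p <- phaseCT:::pad_reflect(I30, 256L, 256L)
  fy <- phaseCT:::fft_freq(256L, 9)
  lam_um <- b$wavelength_A * 1e-4
  G <- 1 / (1 + pi * lam_um * 30e4 * 1950 * outer(fy^2, fy^2, "+"))
  sm <- Re(phaseCT:::ifft2(phaseCT:::fft2(p$m) * G))
  expect_lt(abs(mean(sm) / mean(p$m) - 1), 1e-3)  # < 0.1 %
  expect_lt(abs(mean(sm) / mean(p$m) - 1), 1e-12) # in fact exact: G(0) = 1
})

test_that("weak-object round-trip: retrieval inverts the simulation", {
  ## at weak contrast the linearized TIE forward model is exact and the
  ## retrieved A matches contact -ln(I) even right up to the edge band
  vol <- make_edge_phantom(c(32L, 64L, 64L), delta_tissue = 4.06e-9)
  b <- tiny_beam()
  t0 <- complex_transmission(vol, 0, b)
  A0 <- -log(Mod(t0)^2)
  I30 <- Mod(fresnel_propagate(t0, 30, b$wavelength_A, 9,
                               warn_sampling = FALSE))^2
  A <- retrieve_projection(I30, retrieval_params(1950, 30, 22, 9))
  away <- !(col(A) %in% 30:36)          # 3-px band around the edge at 33
  nrmse <- sqrt(mean((A - A0)[away]^2)) / diff(range(A0))
  expect_lt(nrmse, 0.02)
  ## at realistic lung contrast the sharp edge leaves a larger residual
  ## concentrated near the interface (the blur the reference data shows)
  vol2 <- make_edge_phantom(c(32L, 64L, 64L), delta_tissue = 4.06e-7)
  t2 <- complex_transmission(vol2, 0, b)
  I2 <- Mod(fresnel_propagate(t2, 30, b$wavelength_A, 9,
                              warn_sampling = FALSE))^2
  A2 <- retrieve_projection(I2, retrieval_params(1950, 30, 22, 9))
  res2 <- abs(A2 + log(Mod(t2)^2))
  expect_gt(mean(res2[, 31:35]), 5 * mean(res2[, c(1:10, 54:64)]))
})

test_that("total variation of retrieved images decreases with gamma * R", {
  set.seed(7)
  I <- matrix(exp(rnorm(64^2, sd = 0.02)), 64, 64)
  tv <- function(m) sum(abs(diff(m))) + sum(abs(t(diff(t(m)))))
  tvs <- vapply(c(0, 5, 30, 100), function(R)
    tv(retrieve_projection(I, retrieval_params(1950, R, 22, 9))),
    numeric(1))
  expect_true(all(diff(tvs) < 0))
})

test_that("retrieve_stack applies per angle and guards geometry", {
  vol <- make_lung_phantom(tiny_lung_spec(seed = 2))
  st <- suppressWarnings(simulate_scan(vol, 30, 4, tiny_beam(),
                                       noise = FALSE))[[1]]
  p30 <- retrieval_params(1950, 30, 22, 9)
  rs <- retrieve_stack(st, p30)
  expect_equal(dim(rs$images), dim(st$intensities))
  expect_equal(rs$images[2, , ],
               retrieve_projection(st$intensities[2, , ], p30))
  p100 <- retrieval_params(1950, 100, 22, 9)
  expect_error(retrieve_stack(st, p100), "mismatch")
  expect_s3_class(retrieve_stack(st, p100, override = TRUE),
                  "retrieved_stack")
})

test_that("bone imaged with the lung gamma stays blurrier than lung", {
  ## gamma mismatch (true 250, retrieval 1950) leaves residual blur:
  ## compare retrieved edge widths of equal-delta half-space phantoms
  ## weak-object regime, where the net edge transfer function
  ## (1 + pi lam R gamma_true f^2) / (1 + pi lam R gamma_retrieval f^2)
  ## is the whole story: matched gamma reconstructs the sharp edge,
  ## mismatched bone-like gamma leaves a low-pass residual
  b <- tiny_beam()
  edge_k2 <- function(gamma_true) {
    vol <- make_edge_phantom(c(32L, 64L, 64L), gamma = gamma_true,
                             delta_tissue = 4.06e-9)
    t0 <- complex_transmission(vol, 0, b)
    I <- Mod(fresnel_propagate(t0, 100, b$wavelength_A, 9,
                               warn_sampling = FALSE))^2
    A <- retrieve_projection(I, retrieval_params(1950, 100, 22, 9))
    pr <- structure(list(positions_mm = (seq_len(64) - 1) * 9e-3,
                         values = colMeans(A), n_averaged = 32,
                         length_mm = 63 * 9e-3), class = "line_profile")
    fit_sigmoid(pr)$k2
  }
  expect_gt(edge_k2(1950), 1.5 * edge_k2(250))
})

test_that("attenuation_to_delta converts and scales linearly", {
  lam <- 12.39842 / 22
  ## mu = 10 / cm = 1e-3 / um -> delta = 8.745e-6 (independent oracle)
  expect_equal(attenuation_to_delta(1e-3, 1950, lam), 8.745173e-6,
               tolerance = 1e-6)
  expect_equal(attenuation_to_delta(0, 1950, lam), 0)
  expect_equal(attenuation_to_delta(2e-3, 1950, lam),
               2 * attenuation_to_delta(1e-3, 1950, lam))
  expect_error(attenuation_to_delta(1, 0, lam), "gamma")
})
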