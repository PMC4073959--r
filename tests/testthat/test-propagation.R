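test_that("wavelength follows lambda = hc / E", {
  b <- beam_spec(22)
  expect_equal(b$wavelength_A, 12.39842 / 22, tolerance = 1e-9)
  expect_equal(energy_to_wavelength(22), 0.563565, tolerance = 1e-6)
  expect_error(beam_spec(-1))
})

test_that("empty and pure-phase volumes transmit as expected", {
  shape <- c(8L, 48L, 48L)
  empty <- complex_index_volume(array(0, shape), array(0, shape),
                                array(0L, shape), 9)
  t0 <- complex_transmission(empty, 12.5, tiny_beam())
  expect_equal(max(Mod(t0 - 1)), 0, tolerance = 1e-14)
  phase_only <- complex_index_volume(array(1e-7, shape), array(0, shape),
                                     array(1L, shape), 9)
  tp <- complex_transmission(phase_only, 45, tiny_beam())
  expect_lt(max(abs(Mod(tp) - 1)), 1e-12)
  expect_error(complex_transmission(empty, 360, tiny_beam()), "angle")
})

test_that("uniform slab obeys Beer-Lambert through |t|^2", {
  vol <- make_edge_phantom(c(32L, 64L, 32L), voxel_size = 9,
                           delta_tissue = 4.06e-7)
  t0 <- complex_transmission(vol, 0, tiny_beam())
  lam_um <- 12.39842 / 22 * 1e-4
  mu <- 4 * pi * (4.06e-7 / 1950) / lam_um
  ## rays through the tissue half traverse the full 32-voxel depth
  expect_equal(Mod(t0[16, 60])^2, exp(-mu * 32 * 9), tolerance = 1e-10)
  ## air-side rays are unattenuated
  expect_equal(Mod(t0[16, 5])^2, 1, tolerance = 1e-12)
})

test_that("Fresnel propagator is unitary and identity at R = 0", {
  set.seed(1)
  f <- matrix(complex(real = rnorm(64^2), imaginary = rnorm(64^2)), 64, 64)
  expect_identical(fresnel_propagate(f, 0, 0.56356, 9), f)
  fR <- fresnel_propagate(f, 30, 0.56356, 9, pad = FALSE,
                          warn_sampling = FALSE)
  expect_lt(abs(sum(Mod(fR)^2) / sum(Mod(f)^2) - 1), 1e-10)
  ## uniform field is unchanged up to a global phase
  u <- matrix(1 + 0i, 32, 32)
  uR <- fresnel_propagate(u, 100, 0.56356, 9, pad = FALSE,
                          warn_sampling = FALSE)
  expect_lt(max(Mod(uR / uR[1, 1] - 1)), 1e-12)
})

test_that("sub-pixel first fringe triggers the sampling warning", {
  f <- matrix(1 + 0i, 32, 32)
  expect_warning(fresnel_propagate(f, 30, 0.56356, 9), "undersampled")
  expect_silent(fresnel_propagate(f, 30, 0.56356, 0.5, warn_sampling = TRUE))
})

test_that("absorption-only phantom shows no fringes away from edges", {
  vol <- make_disk_phantom(c(2L, 64L, 64L), mu_disk = 5, radius_frac = 0.3)
  b <- tiny_beam()
  t0 <- complex_transmission(vol, 0, b)
  I0 <- Mod(t0)^2
  ## an amplitude step still diffracts (exact Fresnel propagation, not the
  ## first-order TIE); ripples stay a sub-percent fraction of the
  ## absorption contrast and vanish at contact
  contrast <- diff(range(I0))
  for (R in c(7, 100)) {
    IR <- Mod(fresnel_propagate(t0, R, b$wavelength_A, 9,
                                warn_sampling = FALSE))^2
    rim <- abs(seq_len(64) - 32.5)
    away <- rim < 14 | rim > 25
    expect_lt(max(abs(IR - I0)[, away]) / contrast, 0.01)
  }
  expect_identical(fresnel_propagate(t0, 0, b$wavelength_A, 9), t0)
})

test_that("edge overshoot grows monotonically with distance", {
  vol <- make_edge_phantom(c(32L, 64L, 64L))
  t0 <- complex_transmission(vol, 0, tiny_beam())
  overshoot <- vapply(c(0, 7, 30, 100), function(R) {
    I <- Mod(fresnel_propagate(t0, R, tiny_beam()$wavelength_A, 9,
                               warn_sampling = FALSE))^2
    max(I) - 1
  }, numeric(1))
  expect_lt(overshoot[1], 1e-9)
  expect_true(all(diff(overshoot) > 0))
})

test_that("detector: exact intensity, Poisson statistics, determinism", {
  f <- matrix(complex(modulus = sqrt(0.9), argument = 0.3), 50, 50)
  b <- tiny_beam()
  expect_equal(detect(f, b, noise = FALSE), Mod(f)^2)
  bn <- tiny_beam(1e4)
  I1 <- detect(f, bn, seed = 42)
  I2 <- detect(f, bn, seed = 42)
  expect_identical(I1, I2)
  ## relative sd ~ 1/sqrt(N I): 1/sqrt(9000) = 1.05e-2
  expect_equal(sd(I1) / mean(I1), 1 / sqrt(1e4 * 0.9), tolerance = 0.1)
  expect_error(detect(f, bn), "seed")
})

test_that("simulate_scan angle grid, folding exactness and determinism", {
  vol <- make_lung_phantom(tiny_lung_spec(seed = 3))
  b <- tiny_beam()
  st <- suppressWarnings(simulate_scan(vol, 30, 4, b, noise = FALSE))[[1]]
  expect_equal(st$angles, c(0, 90, 180, 270))
  expect_equal(dim(st$intensities)[1], 4L)
  ## folded opposing view equals a directly computed one
  t180 <- complex_transmission(vol, 180, b)
  I180 <- Mod(fresnel_propagate(t180, 30, b$wavelength_A, 9,
                                warn_sampling = FALSE))^2
  expect_lt(max(abs(st$intensities[3, , ] - I180)), 1e-12)
  ## contact regime: no edge overshoot above 1
  st0 <- simulate_scan(vol, 0, 2, b, noise = FALSE)[[1]]
  expect_lt(max(st0$intensities) - 1, 1e-9)
  ## noisy scans are seed-deterministic
  bn <- tiny_beam(5000)
  s1 <- suppressWarnings(simulate_scan(vol, 30, 2, bn, seed = 9))[[1]]
  s2 <- suppressWarnings(simulate_scan(vol, 30, 2, bn, seed = 9))[[1]]
  expect_identical(s1$intensities, s2$intensities)
})

test_that("detector binning integrates intensity over pixel blocks", {
  m <- matrix(seq_len(16), 4, 4)
  expect_equal(phaseCT:::bin_matrix(m, 2),
               matrix(c(mean(m[1:2, 1:2]), mean(m[3:4, 1:2]),
                        mean(m[1:2, 3:4]), mean(m[3:4, 3:4])), 2, 2))
  vol <- make_lung_phantom(tiny_lung_spec(seed = 4))
  st <- suppressWarnings(simulate_scan(vol, 30, 2, tiny_beam(),
                                       noise = FALSE, bin = 2L))[[1]]
  expect_equal(dim(st$intensities)[2:3], c(4L, 24L))
  expect_equal(st$pixel_size_um, 18)
})

test_that("projection stack serialization round-trips, noise on and off", {
  vol <- make_lung_phantom(tiny_lung_spec(seed = 6))
  dirp <- withr::local_tempdir()
  for (b in list(tiny_beam(), tiny_beam(4000))) {
    st <- suppressWarnings(simulate_scan(vol, 30, 3, b, seed = 5))[[1]]
    stem <- file.path(dirp, paste0("st", is.finite(b$photons_per_pixel)))
    write_stack(st, stem)
    back <- read_stack(stem)
    expect_equal(back$intensities, st$intensities)
    expect_equal(back$angles, st$angles)
    expect_equal(back$beam$photons_per_pixel, b$photons_per_pixel)
  }
})

test_that("apply_noise reproduces the in-scan Poisson draw contract", {
  vol <- make_lung_phantom(tiny_lung_spec(seed = 8))
  st0 <- suppressWarnings(simulate_scan(vol, 30, 2, tiny_beam(),
                                        noise = FALSE))[[1]]
  n1 <- apply_noise(st0, seed = 3, photons_per_pixel = 2000)
  n2 <- apply_noise(st0, seed = 3, photons_per_pixel = 2000)
  expect_identical(n1$intensities, n2$intensities)
  expect_true(n1$noise_applied)
  expect_true(all(n1$intensities > 0))
  expect_error(apply_noise(n1, seed = 1))
})
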