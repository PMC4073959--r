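test_that("mean_filter_3d: constant, impulse and mean preservation", {
  v <- array(3, c(5, 5, 5))
  expect_equal(mean_filter_3d(v), v)
  imp <- array(0, c(7, 7, 7)); imp[4, 4, 4] <- 1
  f <- mean_filter_3d(imp)
  expect_equal(sum(f > 0), 27L)
  expect_equal(max(f), 1 / 27, tolerance = 1e-12)
  set.seed(2)
  r <- array(runif(6^3), c(6, 6, 6))
  ## reflecting boundaries redistribute but interior-weighted sums keep the
  ## global mean to first order; check exactly on a wrap-free interior
  fr <- mean_filter_3d(r)
  expect_equal(fr[3, 3, 3], mean(r[2:4, 2:4, 2:4]), tolerance = 1e-12)
})

test_that("find_matching_slice locates exact, inverted and noisy copies", {
  ref <- random_smooth_image(4, n = 48)
  vol <- array(0, c(25, 48, 48))
  set.seed(6)
  for (k in 1:25) vol[k, , ] <- matrix(runif(48^2), 48, 48) * 0.5
  vol[17, , ] <- ref
  m <- find_matching_slice(ref, vol)
  expect_identical(m$index, 17L)
  expect_equal(m$score, 1, tolerance = 1e-12)
  mneg <- find_matching_slice(-ref, vol[17, , , drop = FALSE])
  expect_equal(mneg$score, -1, tolerance = 1e-12)
  ## reference + 10%-of-range gaussian noise still matches index 17
  set.seed(8)
  vol[17, , ] <- ref + rnorm(48^2, sd = 0.1 * diff(range(ref)))
  expect_identical(find_matching_slice(ref, vol)$index, 17L)
  ## ties break to the lowest index
  vol2 <- array(rep(ref, each = 3), c(3, 48, 48))
  expect_identical(find_matching_slice(ref, vol2)$index, 1L)
  expect_error(find_matching_slice(ref, array(0, c(0, 48, 48))), "empty")
})

test_that("fourier_mellin: identity and known-transform recovery", {
  fixed <- random_smooth_image(3, n = 128, passes = 6)
  est0 <- fourier_mellin(fixed, fixed)
  expect_equal(est0$scale, 1, tolerance = 1e-3)
  expect_equal(est0$rotation_deg, 0, tolerance = 0.1)
  expect_equal(est0$translation, c(0, 0), tolerance = 0.1)
  expect_gt(est0$score, 0.99)

  ## apply (rotation 30 deg, scale 1.2, shift (5, 3)) and recover it
  n <- 128; cr <- (n + 1) / 2; th <- 30 * pi / 180
  gr <- rep(1:n, times = n) - cr; gc <- rep(1:n, each = n) - cr
  sr <- (cos(th) * gr - sin(th) * gc) * 1.2 + cr + 5
  sc <- (sin(th) * gr + cos(th) * gc) * 1.2 + cr + 3
  moving <- matrix(phaseCT:::bilinear_sample(fixed, sr, sc), n, n)
  est <- fourier_mellin(fixed, moving)
  expect_lt(abs(est$rotation_deg - 30), 0.5)
  expect_lt(abs(est$scale / 1.2 - 1), 0.01)
  expect_lt(max(abs(est$translation - c(5, 3))), 0.5)
  ## aligning with the estimate reproduces the fixed image
  aligned <- apply_transform(moving, est)
  msk <- attr(aligned, "mask")
  expect_gt(cor(aligned[msk], fixed[msk]), 0.95)
})

test_that("non-convergence below the score threshold is flagged", {
  set.seed(11)
  a <- matrix(runif(64^2), 64, 64)
  b <- matrix(runif(64^2), 64, 64)   # unrelated content
  expect_warning(tr <- fourier_mellin(a, b, min_score = 0.9), "below")
  expect_false(attr(tr, "converged"))
})

test_that("apply_transform: identity, integer shifts, round trips", {
  img <- random_smooth_image(9, n = 64)
  idt <- apply_transform(img, registration_transform())
  msk <- attr(idt, "mask")
  expect_equal(idt[msk], img[msk], tolerance = 1e-12)
  sh <- apply_transform(img, registration_transform(translation = c(4, -2)))
  mm <- attr(sh, "mask")
  expect_equal(sh[5:64, 1:62][mm[5:64, 1:62]],
               img[1:60, 3:64][mm[5:64, 1:62]], tolerance = 1e-12)
  ## T then T^-1 on the interior
  tr <- registration_transform(scale = 1.1, rotation_deg = 20,
                               translation = c(2, 1))
  fwd <- apply_transform(img, tr)
  inv <- registration_transform(scale = 1 / 1.1, rotation_deg = -20)
  back <- apply_transform(
    apply_transform(fwd, registration_transform(
      translation = -tr$translation)), inv)
  interior <- matrix(FALSE, 64, 64); interior[20:45, 20:45] <- TRUE
  ok <- interior & attr(back, "mask")
  expect_lt(sqrt(mean((back[ok] - img[ok])^2)) / diff(range(img)), 0.01)
})

test_that("register_volumes recovers identity on matched recon volumes", {
  vol <- make_lung_phantom(phantom_spec(shape = c(12L, 64L, 64L),
                                        vesicle_count = 30L, seed = 21))
  st <- suppressWarnings(simulate_scan(vol, c(7, 30), 48, tiny_beam(),
                                       noise = FALSE))
  ref <- reconstruct_volume(st[[1]], rows = 5:8)
  mov <- reconstruct_volume(
    retrieve_stack(st[[2]], retrieval_params(1950, 30, 22, 9)), rows = 5:8)
  tr <- register_volumes(ref, mov)
  expect_lt(abs(tr$rotation_deg), 1)
  expect_lt(abs(tr$scale - 1), 0.02)
  expect_lt(max(abs(tr$translation)), 1)
})

test_that("transforms serialize to the documented JSON schema", {
  tr <- registration_transform(1.05, -3, c(1.5, -2), 0.87, 4L)
  path <- file.path(withr::local_tempdir(), "t.json")
  write_transform(tr, path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(j$scale, 1.05)
  expect_equal(j$rotation_deg, -3)
  expect_equal(j$translation_px, c(1.5, -2))
  expect_equal(j$matched_slice, 4L)
})
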