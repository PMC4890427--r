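test_that("discard_initial drops frames and composes additively", {
  set.seed(1)
  run <- bold_run(array(rnorm(4^3 * 240), dim = c(4, 4, 4, 240)), 2)
  out <- discard_initial(run, 10)
  expect_identical(dim(out$data)[4], 230L)
  expect_equal(out$data[, , , 1], run$data[, , , 11])
  expect_equal(discard_initial(run, 0), run)
  expect_error(discard_initial(run, 240), "cannot discard")
  # composition property
  a <- discard_initial(discard_initial(run, 3), 4)
  b <- discard_initial(run, 7)
  expect_equal(a$data, b$data)
})

test_that("motion_screen applies exclusive 3 mm / 3 degree limits", {
  t29 <- matrix(0, 50, 3); t29[20, 2] <- 2.9
  r29 <- matrix(0, 50, 3); r29[10, 3] <- -2.9
  expect_true(motion_screen(motion_params(t29, r29))$pass)
  # above limit on y -> fail, axis reported
  t31 <- t29; t31[5, 2] <- -3.1
  res <- motion_screen(motion_params(t31, r29))
  expect_false(res$pass)
  expect_identical(res$failed_axes, "y")
  # exactly 3.0 mm passes (strict "more than" reading)
  t30 <- matrix(0, 50, 3); t30[7, 1] <- 3.0
  expect_true(motion_screen(motion_params(t30, r29))$pass)
  expect_error(motion_params(t29 * NA, r29), "non-finite")
})

test_that("motion params round-trip through the 6-column text format", {
  set.seed(2)
  m <- cbind(matrix(rnorm(30, 0, 0.5), 10), matrix(rnorm(30, 0, 0.3), 10))
  path <- tempfile()
  write.table(m, path, row.names = FALSE, col.names = FALSE)
  mp <- read_motion_params(path)
  expect_equal(unname(mp$translations), m[, 1:3], tolerance = 1e-12)
  unlink(path)
})

test_that("gaussian smoothing matches the analytic kernel and conserves mean", {
  # delta impulse: center value equals the product of 1D center weights of
  # the normalized discrete kernel (independent oracle computed here)
  fwhm <- 6; voxel <- 3
  sigma <- (fwhm / voxel) / (2 * sqrt(2 * log(2)))   # ~0.849 voxels
  r <- max(1, ceiling(4 * sigma))
  k1d <- exp(-((-r):r)^2 / (2 * sigma^2)); k1d <- k1d / sum(k1d)
  arr <- array(0, c(11, 11, 11)); arr[6, 6, 6] <- 1
  sm <- smooth_gaussian(arr, fwhm_mm = fwhm, voxel_mm = voxel)
  expect_equal(sm[6, 6, 6], k1d[r + 1]^3, tolerance = 1e-12)
  expect_equal(sm[6, 6, 5], k1d[r + 1]^2 * k1d[r], tolerance = 1e-12)
  # mean conservation under reflective boundaries
  set.seed(4)
  arr2 <- array(rnorm(9^3), c(9, 9, 9))
  sm2 <- smooth_gaussian(arr2, 8, voxel_mm = 3)
  expect_equal(mean(sm2), mean(arr2), tolerance = 1e-10)
  # identity and constancy
  expect_equal(smooth_gaussian(arr2, 0, voxel_mm = 3), arr2)
  cst <- array(2.5, c(8, 8, 8))
  expect_equal(smooth_gaussian(cst, 6, voxel_mm = 3), cst, tolerance = 1e-12)
  expect_error(smooth_gaussian(arr2, -1, voxel_mm = 3), ">= 0")
})

test_that("smoothing commutes with affine rescaling of intensities", {
  set.seed(5)
  arr <- array(rnorm(8^3), c(8, 8, 8))
  a <- smooth_gaussian(3 * arr + 1, 6, voxel_mm = 3)
  b <- 3 * smooth_gaussian(arr, 6, voxel_mm = 3) + 1
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("detrend_and_bandpass removes trends and has the stated response", {
  tr <- 2; n <- 230
  tt <- seq_len(n)
  # pure ramp -> zero
  ramp <- matrix(5 + 0.3 * tt, nrow = 1)
  expect_lt(max(abs(detrend_and_bandpass(ramp, tr))), 1e-8)
  # 0.05 Hz sinusoid retained >= 95%
  s_in <- sin(2 * pi * 0.05 * tt * tr)
  out <- detrend_and_bandpass(matrix(s_in, 1), tr)
  expect_gte(sd(out) / sd(s_in), 0.95)
  # 0.2 Hz sinusoid suppressed <= 5%
  s_hi <- sin(2 * pi * 0.2 * tt * tr)
  out_hi <- detrend_and_bandpass(matrix(s_hi, 1), tr)
  expect_lte(sd(out_hi) / sd(s_hi), 0.05)
  # zero-mean rows, idempotency of the frequency mask
  set.seed(6)
  X <- matrix(rnorm(5 * n), 5)
  f1 <- detrend_and_bandpass(X, tr)
  f2 <- detrend_and_bandpass(f1, tr, detrend = FALSE)  # the filter itself
  expect_lt(max(abs(rowMeans(f1))), 1e-10)
  expect_lt(max(abs(f2 - f1)), 1e-6)
  # invalid bands
  expect_error(detrend_and_bandpass(X, tr, band_hz = c(0.05, 0.3)), "Nyquist")
  expect_error(detrend_and_bandpass(X, tr, band_hz = c(0.08, 0.01)), "band")
})
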