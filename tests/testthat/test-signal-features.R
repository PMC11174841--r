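test_that("low-pass filter has unity DC gain and the Butterworth cutoff gain", {
  # constant (DC) input passes unchanged
  dc <- accel_stream(matrix(2.5, 1000, 12), rate = 100)
  expect_lt(max(abs(lowpass_filter(dc)$data - 2.5)), 1e-6)
  expect_lt(max(abs(lowpass_filter(dc, zero_phase = FALSE)$data - 2.5)), 1e-6)

  # single causal pass: |H| = 1/sqrt(2) at the 20 Hz cutoff, any order
  s20 <- sine_stream(freq = 20, seconds = 50)
  y <- lowpass_filter(s20, zero_phase = FALSE)$data[, 1]
  a20 <- component_amplitude(y, 20, 100, 3000, 2000)
  expect_equal(a20, 1 / sqrt(2), tolerance = 0.01)

  # zero-phase (forward-backward) squares the magnitude response
  yz <- lowpass_filter(s20)$data[, 1]
  expect_equal(component_amplitude(yz, 20, 100, 1500, 2000), 0.5,
               tolerance = 0.01)

  # 40 Hz is deep in the stopband after zero-phase filtering
  s40 <- sine_stream(freq = 40, seconds = 50)
  y40 <- lowpass_filter(s40)$data[, 1]
  expect_lt(component_amplitude(y40, 40, 100, 1500, 2000), 0.01)

  # cutoff at/above Nyquist rejected
  expect_error(lowpass_filter(s20, cutoff_hz = 50), "Nyquist")
})

test_that("filtering is linear and applied per channel", {
  set.seed(42)
  x <- matrix(rnorm(500 * 12), 500, 12)
  y <- matrix(rnorm(500 * 12), 500, 12)
  fx <- lowpass_filter(accel_stream(x))$data
  fy <- lowpass_filter(accel_stream(y))$data
  fxy <- lowpass_filter(accel_stream(2 * x - 3 * y))$data
  expect_lt(max(abs(fxy - (2 * fx - 3 * fy))), 1e-6)

  # channel independence: changing one channel leaves the others untouched
  x2 <- x; x2[, 5] <- rnorm(500)
  fx2 <- lowpass_filter(accel_stream(x2))$data
  expect_identical(fx2[, -5], fx[, -5])
})

test_that("windowing yields non-overlapping contiguous windows, partial tail dropped", {
  s <- sine_stream(freq = 2, seconds = 35)
  w <- window_stream(s, 10)
  expect_length(w, 3)
  expect_true(all(vapply(w, function(x) nrow(x$data), 0L) == 1000L))
  # partition property: concatenation reproduces the stream prefix
  expect_identical(do.call(rbind, lapply(w, `[[`, "data")),
                   s$data[1:3000, ])

  expect_length(window_stream(sine_stream(seconds = 10), 10), 1)
  expect_error(window_stream(sine_stream(seconds = 9.99), 10), "shorter")
})

test_that("mean absolute deviation matches hand values and a brute-force loop", {
  expect_equal(mean_abs_dev(c(1, 2, 3, 4)), 1.0)
  expect_equal(mean_abs_dev(rep(7, 3)), 0.0)
  expect_equal(mean_abs_dev(c(0, 10)), 5.0)
  expect_error(mean_abs_dev(numeric(0)), "empty")

  brute <- function(x) {
    m <- sum(x) / length(x)
    acc <- 0
    for (v in x) acc <- acc + abs(v - m)
    acc / length(x)
  }
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(sample(2:50, 1), sd = runif(1, 0.1, 10))
    expect_equal(mean_abs_dev(x), brute(x), tolerance = 1e-12)
    # translation invariance and absolute homogeneity
    expect_equal(mean_abs_dev(x + 3.7), mean_abs_dev(x), tolerance = 1e-10)
    expect_equal(mean_abs_dev(-2.5 * x), 2.5 * mean_abs_dev(x),
                 tolerance = 1e-10)
  }
})

test_that("feature extraction gives 12 ordered MADs plus BMI", {
  zero_win <- window_stream(accel_stream(matrix(0, 1000, 12)), 10)[[1]]
  f <- extract_features(zero_win, bmi = 24.5)
  expect_length(f, 13)
  expect_equal(unname(f), c(rep(0, 12), 24.5), ignore_attr = TRUE)
  expect_false(attr(f, "normalized"))

  # only chest-x non-constant -> exactly one non-zero MAD, at position 1
  d <- matrix(1, 1000, 12); d[, 1] <- sin(1:1000)
  w <- window_stream(accel_stream(d), 10)[[1]]
  f2 <- extract_features(w, 24.5)
  expect_gt(f2[1], 0)
  expect_equal(unname(f2[2:12]), rep(0, 11), ignore_attr = TRUE)

  # determinism
  expect_identical(extract_features(w, 24.5), extract_features(w, 24.5))
  expect_error(extract_features(w, bmi = -1), "bmi")
})

test_that("z-score normalizer: fit, apply, invert, degeneracy", {
  x <- random_features(30)
  nm <- fit_normalizer(x)
  z <- apply_normalizer(x, nm)
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_lt(max(abs(sqrt(colMeans(sweep(z, 2, colMeans(z))^2)) - 1)), 1e-9)
  expect_true(attr(z, "normalized"))

  # round trip
  expect_lt(max(abs(invert_normalizer(z, nm) - x)), 1e-9)

  # feature equal to the stored means -> all zeros; mean + 1 sd -> all ones
  expect_equal(unname(apply_normalizer(nm$mean, nm)), rep(0, 13),
               ignore_attr = TRUE)
  expect_equal(unname(apply_normalizer(nm$mean + nm$sd, nm)), rep(1, 13),
               ignore_attr = TRUE)

  # double normalization guarded
  expect_error(apply_normalizer(z, nm), "already normalized")
  # dimension mismatch
  expect_error(apply_normalizer(c(1, 2), nm), "dimension")
  # zero-variance feature named by index
  bad <- x; bad[, 4] <- 1
  expect_error(fit_normalizer(bad), "index 4")
})

test_that("accelerometer CSV round-trips through read/write", {
  s <- sine_stream(freq = 1:12, seconds = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_accel_csv(s, path)
  s2 <- read_accel_csv(path)
  expect_equal(s2$rate, 100, tolerance = 1e-9)
  expect_equal(s2$data, s$data, tolerance = 1e-6, ignore_attr = TRUE)
})
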