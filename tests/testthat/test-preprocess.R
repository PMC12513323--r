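test_that("rr_from_peaks takes first differences and validates input", {
  b <- rr_from_peaks(c(0.0, 0.8, 1.6, 2.5))
  expect_equal(b$rr, c(0.8, 0.8, 0.9))
  expect_equal(length(b$rr), length(b$peak_times) - 1L)
  expect_error(rr_from_peaks(c(0.0, 0.4)), "at least 3")
  expect_error(rr_from_peaks(c(0, 1, 0.5, 2)), "index 3")
  # simulated 150 bpm train
  cfg <- subject_config("infant", hr_mean = 150, rsa_gain = 0, lf_gain = 0,
                        noise_sd = 0, seed = 1)
  rec <- make_recording(cfg, 120)
  expect_true(all(abs(rr_from_peaks(rec$peak_times)$rr - 0.4) < 0.01))
})

test_that("artifact correction recovers an injected ectopic-like interval", {
  tt <- cumsum(c(0, rep(0.8, 100)))
  b <- rr_from_peaks(tt)
  b$rr[50] <- 0.2
  out <- correct_artifacts(b)
  expect_equal(out$n_corrected, 1L)
  expect_lt(abs(out$rr[50] - 0.8), 0.02)
  # clean series is a no-op
  clean <- correct_artifacts(rr_from_peaks(tt))
  expect_identical(clean$rr, rr_from_peaks(tt)$rr)
  expect_equal(clean$n_corrected, 0L)
  # heavy corruption rejects the window
  set.seed(1)
  bad <- rr_from_peaks(tt)
  k <- sample(100, 30)
  bad$rr[k] <- bad$rr[k] * sample(c(0.3, 2.5), 30, replace = TRUE)
  expect_error(correct_artifacts(bad), "unanalyzable")
})

test_that("smoothness-priors detrend removes polynomials and matches the dense oracle", {
  ramp <- seq(0, 10, length.out = 200)
  expect_lt(max(abs(detrend_smoothness_priors(ramp))), 1e-6 * 10)
  expect_equal(detrend_smoothness_priors(rep(3.7, 150)), rep(0, 150),
               tolerance = 1e-10)
  # in-band sinusoid passes nearly unattenuated
  t4 <- seq(0, 180, by = 0.25)
  y <- 2 * t4 / 180 + 0.5 * sin(2 * pi * 0.3 * t4)
  d <- detrend_smoothness_priors(y)
  amp <- sqrt(2 * mean(d^2))
  expect_lt(abs(amp - 0.5) / 0.5, 0.10)
  # linearity
  set.seed(2)
  y1 <- rnorm(120); y2 <- rnorm(120)
  lhs <- detrend_smoothness_priors(3 * y1 - 2 * y2)
  rhs <- 3 * detrend_smoothness_priors(y1) - 2 * detrend_smoothness_priors(y2)
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-10)
  # dense-matrix oracle
  for (n in c(50, 200, 500)) {
    y <- rnorm(n)
    expect_lt(max(abs(detrend_smoothness_priors(y) - dense_detrend(y))) /
                max(abs(y)), 1e-8)
  }
  expect_error(detrend_smoothness_priors(c(1, NA, 3)), "non-finite")
})

test_that("RRi resampling yields a 4 Hz grid with preserved modulation", {
  # constant rr: detrended series is ~0 everywhere
  b <- rr_from_peaks(cumsum(c(0, rep(0.8, 250))))
  rri <- resample_rri(b, detrend_smoothness_priors(b$rr))
  expect_equal(rri$fs, 4)
  expect_lt(max(abs(rri$values)), 1e-8)
  # 180 s of beats -> 720 +- 1 samples and duration preserved
  expect_equal(length(rri$values), 4 * (b$peak_times[251] - b$peak_times[2]) + 1,
               tolerance = 1)
  span_in <- b$peak_times[251] - b$peak_times[2]
  span_out <- (length(rri$values) - 1) / rri$fs
  expect_lt(abs(span_in - span_out), 1 / rri$fs)
  # sinusoidally modulated rr shows its spectral peak at the right place
  tt <- cumsum(c(0, 0.8 * (1 + 0.05 * sin(2 * pi * 0.25 * cumsum(rep(0.8, 250))))))
  b2 <- rr_from_peaks(tt)
  rri2 <- resample_rri(b2, detrend_smoothness_priors(b2$rr))
  ps <- welch_psd(rri2, seg_len = 60)
  expect_lt(abs(ps$freqs[which.max(ps$psd)] - 0.25), 0.02)
  expect_error(resample_rri(rr_from_peaks(c(0, 0.8, 1.6))), "30 s")
})

test_that("infant respiration pipeline normalizes and preserves the dominant frequency", {
  t62 <- seq(0, 180, by = 1 / 62.5)
  raw <- uniform_series(5 + 3 * sin(2 * pi * 0.8 * t62), 62.5, label = "RESP")
  out <- preprocess_infant_resp(raw)
  expect_equal(out$fs, 4)
  expect_lt(abs(mean(out$values)), 1e-8)
  expect_equal(stats::sd(out$values), 1, tolerance = 0.01)
  ps <- welch_psd(out, seg_len = 60)
  expect_lt(abs(ps$freqs[which.max(ps$psd)] - 0.8), 0.05)
  # DC offset is immaterial
  raw2 <- uniform_series(raw$values + 100, 62.5, label = "RESP")
  out2 <- preprocess_infant_resp(raw2)
  expect_lt(max(abs(out$values - out2$values)), 1e-6)
  # degenerate inputs
  expect_error(preprocess_infant_resp(uniform_series(rep(1, 1000), 62.5)),
               "flatline")
  expect_error(preprocess_infant_resp(uniform_series(rnorm(100), 8)), "16 Hz")
})

test_that("infant pipeline tail is near-idempotent for in-band sinusoids", {
  t62 <- seq(0, 180, by = 1 / 62.5)
  raw <- uniform_series(sin(2 * pi * 0.8 * t62), 62.5, label = "RESP")
  once <- preprocess_infant_resp(raw)
  t32 <- seq(0, max(series_times(once)), by = 1 / 32)
  again <- preprocess_infant_resp(uniform_series(
    stats::spline(series_times(once), once$values, xout = t32)$y, 32))
  n <- min(length(once$values), length(again$values))
  expect_gt(stats::cor(once$values[1:n], again$values[1:n]), 0.99)
})
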