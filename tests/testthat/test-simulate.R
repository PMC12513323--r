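test_that("respiration simulator honours its spectral specification", {
  cfg <- subject_config("adult", resp_freq = 0.25, noise_sd = 0, seed = 35)
  # drift-free check: freeze the random walk by zeroing noise and reading truth
  resp <- simulate_respiration(cfg, 180)
  tr <- attr(resp, "truth")
  expect_equal(length(resp$values), 180 * 8)
  expect_true(all(abs(tr$drift) <= 0.2))
  inf_cfg <- subject_config("infant", seed = 36)
  ri <- simulate_respiration(inf_cfg, 180)
  ps <- welch_psd(ri, seg_len = 60)
  fdom <- ps$freqs[which.max(ps$psd)]
  expect_gte(fdom, 0.65)
  expect_lte(fdom, 1.05)
  expect_error(simulate_respiration(cfg, 30), "60 s")
})

test_that("reverse coupling leaks cardiac fluctuation into respiration", {
  cfg_rev <- subject_config("adult", reverse_gain = 0.5, noise_sd = 0,
                            lf_gain = 0.06, seed = 37)
  cfg_none <- subject_config("adult", reverse_gain = 0, noise_sd = 0,
                             lf_gain = 0.06, seed = 37)
  lf_pow <- function(cfg) {
    r <- simulate_respiration(cfg, 300)
    ps <- welch_psd(r, seg_len = 100)
    band_power(ps$freqs, ps$psd, c(0.08, 0.11))
  }
  expect_gt(lf_pow(cfg_rev), 10 * lf_pow(cfg_none))
})

test_that("ipfm beats are regular without modulation and rate-correct", {
  cfg <- subject_config("adult", hr_mean = 72, rsa_gain = 0, lf_gain = 0,
                        noise_sd = 0, seed = 38)
  resp <- simulate_respiration(cfg, 120)
  beats <- simulate_beats(cfg, resp)
  rr <- diff(beats)
  expect_lt(stats::sd(rr), 1e-4)
  expect_equal(mean(rr), 60 / 72, tolerance = 1e-3)
  # respiratory modulation shows up at resp_freq in the RR spectrum
  cfg2 <- subject_config("adult", rsa_gain = 0.05, lf_gain = 0,
                         noise_sd = 0, seed = 39, resp_freq = 0.25)
  rec <- make_recording(cfg2, 190)
  w <- prepare_window(rec, 2, 186)
  ps <- welch_psd(w$rri, seg_len = 60)
  expect_lt(abs(ps$freqs[which.max(ps$psd)] - 0.25), 0.03)
  sch <- band_scheme("adult")
  hf2 <- band_metrics(ps, sch)$hf_power
  cfg0 <- subject_config("adult", rsa_gain = 0, lf_gain = 0,
                         noise_sd = 0, seed = 39, resp_freq = 0.25)
  w0 <- prepare_window(make_recording(cfg0, 190), 2, 186)
  hf0 <- band_metrics(welch_psd(w0$rri, seg_len = 60), sch)$hf_power
  expect_gt(hf2, 100 * max(hf0, 1e-12))
})

test_that("in-band rr variance tracks the injected gain ladder", {
  # variance bookkeeping: relative RR amplitude ~ rsa_gain, so in-band
  # power should scale ~ gain^2 (IPFM + resampling attenuate mildly)
  gains <- c(0.25, 0.5, 1) * 0.04
  pow <- vapply(gains, function(g) {
    cfg <- subject_config("adult", rsa_gain = g, lf_gain = 0, noise_sd = 0,
                          seed = 40, resp_freq = 0.25)
    w <- prepare_window(make_recording(cfg, 190), 2, 186)
    ps <- welch_psd(w$rri, seg_len = 60)
    band_power(ps$freqs, ps$psd, c(0.2, 0.3))
  }, numeric(1))
  expect_equal(pow[2] / pow[1], 4, tolerance = 0.5)
  expect_equal(pow[3] / pow[2], 4, tolerance = 0.5)
})

test_that("subject generation is deterministic and condition-structured", {
  cfg <- subject_config("infant", seed = 41)
  prot <- protocol_config(condition_effects = list(music = c(rsa = 1.5)))
  r1 <- generate_subject(cfg, prot)
  r2 <- generate_subject(cfg, prot)
  expect_identical(r1$peak_times, r2$peak_times)
  expect_identical(r1$resp$values, r2$resp$values)
  expect_equal(r1$segments$end[3], 720)
  expect_equal(r1$segments$condition, c("pre", "music", "post"))
  expect_error(protocol_config(pre_dur = 100), "180 s")
})

test_that("music-phase gain boost raises px during music", {
  prot <- protocol_config(condition_effects = list(music = c(rsa = 3)))
  diffs <- vapply(1:6, function(s) {
    cfg <- subject_config("infant", seed = 700 + s)
    rec <- generate_subject(cfg, prot)
    tab <- analyze_subject(rec)
    px <- function(cond) tab$value[tab$condition == cond & tab$metric == "px"]
    px("music") - px("pre")
  }, numeric(1))
  expect_gt(stats::median(diffs), 0)
})

test_that("cohorts draw physiology from the population ranges deterministically", {
  co <- generate_cohort(18, "infant", seed = 42)
  expect_equal(length(co$recordings), 18)
  expect_true(all(co$manifest$resp_freq >= 0.7 & co$manifest$resp_freq <= 1.0))
  expect_true(all(co$manifest$hr_mean >= 140 & co$manifest$hr_mean <= 160))
  co2 <- generate_cohort(18, "infant", seed = 42)
  expect_identical(co$manifest, co2$manifest)
  ad <- generate_cohort(3, "adult", seed = 43)
  expect_true(all(vapply(ad$recordings, function(r) max(r$segments$end),
                         numeric(1)) == 720))
  expect_error(generate_cohort(1, "adult"), "at least 2")
})

test_that("cohort files round-trip through the interchange formats", {
  co <- generate_cohort(2, "adult", seed = 44)
  dir <- tempfile("cohort")
  write_cohort(co, dir)
  pk <- read_peak_times(file.path(dir, "subject_01", "peaks.txt"))
  expect_equal(pk, co$recordings[[1]]$peak_times, tolerance = 1e-6)
  rs <- read_signal_csv(file.path(dir, "subject_01", "resp.csv"), label = "RESP")
  expect_equal(rs$values, co$recordings[[1]]$resp$values, tolerance = 1e-6)
  expect_equal(rs$fs, 32, tolerance = 0.01)
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 2)
  unlink(dir, recursive = TRUE)
})
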