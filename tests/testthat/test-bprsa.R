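test_that("rri anchors implement the T = 1 comparison rule", {
  inc <- seq(1, 2, length.out = 50)
  a <- find_rri_anchors(inc, "decel")
  expect_equal(a$indices, 2:50)
  expect_equal(find_rri_anchors(inc, "accel")$M, 0L)
  # alternating series: anchors interleave
  alt <- rep(c(0, 1), 30)
  up <- find_rri_anchors(alt, "decel")$indices
  dn <- find_rri_anchors(alt, "accel")$indices
  expect_true(all(abs(diff(sort(c(up, dn)))) == 1))
  # ties excluded from both sets
  flat <- c(1, 1, 1, 2, 2, 1)
  expect_false(2 %in% find_rri_anchors(flat, "decel")$indices)
  expect_false(2 %in% find_rri_anchors(flat, "accel")$indices)
  # sinusoid: decel anchors about half of the comparisons
  t4 <- seq(0, 179.75, by = 0.25)
  s <- sin(2 * pi * 0.1 * t4)
  M <- find_rri_anchors(s, "decel")$M
  expect_lt(abs(M - length(s) / 2) / (length(s) / 2), 0.05)
})

test_that("respiratory anchors count one per cycle", {
  t4 <- seq(0, 180, by = 0.25)
  a <- find_resp_anchors(uniform_series(sin(2 * pi * 0.25 * t4), 4), "max",
                         f_resp_max = 0.5)
  expect_equal(a$M, 45, tolerance = 1)
  b <- find_resp_anchors(uniform_series(sin(2 * pi * 0.8 * t4), 4), "max",
                         f_resp_max = 1.5)
  expect_equal(b$M, 144, tolerance = 2)
  # max anchors sit at cycle maxima
  s <- sin(2 * pi * 0.25 * t4)
  expect_true(all(s[a$indices] > 0.97))
  # constant signal yields an invalid empty set
  z <- find_resp_anchors(uniform_series(rep(0, 721) + 0, 4), "max", 0.5)
  expect_equal(z$M, 0L)
  expect_false(z$valid)
})

test_that("prsa_curve equals the explicit-loop oracle", {
  set.seed(16)
  for (rep in 1:10) {
    n <- sample(300:2000, 1)
    y <- rnorm(n)
    trig <- rnorm(n)
    anch <- find_rri_anchors(trig, "decel")
    L <- sample(c(10, 25, 55), 1)
    cur <- prsa_curve(y, anch, L)
    expect_equal(cur$values, brute_prsa(y, anch$indices, L),
                 tolerance = 1e-12)
    expect_equal(length(cur$values), 2 * L)
  }
  # constant target -> constant curve at that value
  anch <- find_rri_anchors(rnorm(500), "accel")
  expect_equal(unique(prsa_curve(rep(3.3, 500), anch, 20)$values), 3.3)
  # zero target -> zero curve
  expect_true(all(prsa_curve(rep(0, 500), anch, 20)$values == 0))
})

test_that("prsa of a periodic trigger preserves the oscillation", {
  set.seed(17)
  t4 <- seq(0, 299.75, by = 0.25)
  clean <- sin(2 * pi * 0.25 * t4)
  noisy <- clean + 0.3 * rnorm(length(t4))
  anch <- find_resp_anchors(uniform_series(noisy, 4), "max", 0.5)
  cur <- prsa_curve(noisy, anch, 55)
  # curve oscillates at 0.25 Hz with near-unit amplitude
  core <- cur$values[30:80]
  expect_equal(max(core) - min(core), 2, tolerance = 0.4)
  # anchors = all samples -> curve collapses to the series mean
  all_anch <- structure(list(indices = 1:length(noisy), kind = "all",
                             M = length(noisy), valid = TRUE),
                        class = "anchor_set")
  flat <- prsa_curve(noisy, all_anch, 55)
  expect_lt(max(abs(flat$values - mean(noisy))), 0.15)
})

test_that("coupling strength is exact for self- and lagged copies", {
  set.seed(18)
  v <- sin(2 * pi * (0:109) / 22) + 0.1 * rnorm(110)
  mk <- function(vals) structure(list(values = vals, k = -55:54,
                                      kind = "rri_accel", M = 50),
                                 class = "prsa_curve")
  self <- coupling_strength(mk(v), mk(v))
  expect_equal(self$max_xcorr, 1, tolerance = 1e-10)
  expect_equal(self$best_lag, 0L)
  # lagged copy recovers the lag
  w <- c(rep(0, 5), v[1:105])
  lag5 <- coupling_strength(mk(v), mk(w))
  expect_equal(lag5$max_xcorr, 1, tolerance = 0.01)
  expect_equal(abs(lag5$best_lag), 5)
  # affine rescaling of either curve changes nothing
  aff <- coupling_strength(mk(3 * v + 7), mk(-2 * w + 1))
  expect_equal(aff$max_xcorr, lag5$max_xcorr, tolerance = 1e-10)
  # zero-variance curve -> missing
  expect_true(is.na(coupling_strength(mk(rep(1, 110)), mk(v))$max_xcorr))
})

test_that("kde mutual information is symmetric, nonnegative and orders dependence", {
  set.seed(19)
  x <- rnorm(110)
  y <- rnorm(110)
  expect_equal(kde_mutual_information(x, y), kde_mutual_information(y, x),
               tolerance = 1e-12)
  expect_gte(kde_mutual_information(x, y), 0)
  # identical curves carry far more information than independent ones
  mi_dep <- kde_mutual_information(x, x)
  mi_ind <- stats::median(replicate(20, kde_mutual_information(rnorm(110), rnorm(110))))
  expect_gt(mi_dep, mi_ind)
})

test_that("independent white-noise curves score low coupling", {
  set.seed(20)
  vals <- replicate(50, {
    trig <- rnorm(800); targ <- rnorm(800)
    anch <- find_rri_anchors(trig, "decel")
    cs <- coupling_strength(prsa_curve(trig, anch, 55),
                            prsa_curve(targ, anch, 55))
    c(cs$max_xcorr, cs$mi)
  })
  expect_lt(stats::median(vals[1, ]), 0.5)
  set.seed(21)
  v <- rnorm(110)
  mk <- function(vals) structure(list(values = vals, k = -55:54,
                                      kind = "x", M = 50), class = "prsa_curve")
  expect_lt(stats::median(vals[2, ]), coupling_strength(mk(v), mk(v))$mi)
})

test_that("bprsa_panel emits four rows and handles degenerate inputs", {
  cfg <- subject_config("adult", seed = 22)
  w <- quick_window(cfg)
  p <- bprsa_panel(w$rri_raw, w$resp, f_resp_max = 0.5)
  expect_equal(nrow(p), 4L)
  expect_setequal(p$direction, c("rri_to_resp", "resp_to_rri"))
  expect_setequal(p$anchor_kind,
                  c("rri_accel", "rri_decel", "resp_max", "resp_min"))
  expect_true(all(p$max_xcorr >= 0 & p$max_xcorr <= 1))
  expect_true(all(p$mi >= 0))
  # constant RRi: rri anchor sets are empty so those rows are missing;
  # resp anchors remain usable but a constant target has no correlation
  const_rri <- uniform_series(rep(0.8, length(w$rri_raw$values)), 4)
  p2 <- bprsa_panel(const_rri, w$resp, f_resp_max = 0.5)
  expect_true(all(is.na(p2$max_xcorr[p2$direction == "rri_to_resp"])))
  expect_true(all(p2$M[p2$direction == "rri_to_resp"] == 0))
  expect_true(all(p2$M[p2$direction == "resp_to_rri"] >= 10))
})

test_that("respiration-driven generator favours the resp-to-rri direction", {
  diffs <- vapply(1:8, function(s) {
    cfg <- subject_config("adult", seed = 600 + s)  # rsa > 0, reverse = 0
    w <- quick_window(cfg)
    p <- bprsa_panel(w$rri_raw, w$resp, f_resp_max = 0.5)
    stats::median(p$max_xcorr[p$direction == "resp_to_rri"]) -
      stats::median(p$max_xcorr[p$direction == "rri_to_resp"])
  }, numeric(1))
  expect_gt(mean(diffs > 0), 0.5)
})
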