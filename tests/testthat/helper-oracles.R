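# Independent brute-force oracles and small simulation helpers shared by
# the tests. Oracles deliberately use dense linear algebra / explicit loops,
# never the package's own computational path.

# dense smoothness-priors detrend: (I - (I + lam^2 D2'D2)^-1) y
dense_detrend <- function(y, lam = 500) {
  n <- length(y)
  D2 <- diff(diag(n), differences = 2)
  as.numeric((diag(n) - solve(diag(n) + lam^2 * t(D2) %*% D2)) %*% y)
}

# dense normal-equations projection of y onto the delay subspace of x,
# with the same mean-removal and causal row alignment as the package
dense_osp <- function(y, x, m) {
  x <- x - mean(x); y <- y - mean(y)
  n <- length(x); nr <- n - m
  V <- matrix(vapply(0:m, function(d) x[(d + 1):(nr + d)], numeric(nr)),
              nrow = nr)
  ya <- y[(m + 1):n]
  P <- V %*% solve(t(V) %*% V) %*% t(V)
  y_x <- as.numeric(P %*% ya)
  list(y_x = y_x, y_perp = ya - y_x, px = sum(y_x^2) / sum(ya^2))
}

# explicit-loop PRSA
brute_prsa <- function(target, anchors, L) {
  idx <- anchors[anchors - L >= 1 & anchors + L - 1 <= length(target)]
  vapply((-L):(L - 1), function(k) mean(target[idx + k]), numeric(1))
}

# single-segment synthetic recording (no protocol structure) for
# window-level tests
make_recording <- function(cfg, dur = 190) {
  resp <- simulate_respiration(cfg, dur)
  peaks <- simulate_beats(cfg, resp)
  t_out <- seq(0, dur - 1 / 32, by = 1 / 32)
  resp32 <- uniform_series(
    stats::spline(series_times(resp), resp$values, xout = t_out)$y,
    fs = 32, label = "RESP")
  list(peak_times = peaks, resp = resp32, truth = attr(resp, "truth"),
       resp8 = resp, cfg = cfg)
}

quick_window <- function(cfg, dur = 190, start = 2) {
  prepare_window(make_recording(cfg, dur), start, dur - 2 * start)
}

# phase series built directly from a phase vector (bypasses filtering)
raw_phase <- function(phi, fs = 4) {
  structure(list(phi = phi, fs = fs, keep = rep(TRUE, length(phi))),
            class = "phase_series")
}
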