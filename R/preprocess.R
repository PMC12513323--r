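#' RR intervals from R-peak times
#'
#' Builds a [beat_series()] whose intervals are first differences of the peak
#' times. Peaks must be strictly increasing and at least three are required.
#'
#' @param peak_times numeric vector of R-peak times in seconds.
#' @return a `beat_series`.
#' @export
rr_from_peaks <- function(peak_times) beat_series(peak_times)

#' Automated RR artifact correction
#'
#' Deterministic replacement for manual artifact editing: an interval whose
#' relative deviation from the median of the 11 surrounding intervals exceeds
#' `tol` is flagged and replaced by cubic interpolation from the unflagged
#' neighbours. A window where more than 20% of intervals are flagged is
#' rejected as unanalyzable.
#'
#' @param beats a `beat_series`.
#' @param tol relative deviation threshold, in (0, 1). Default 0.25.
#' @param max_flagged maximum tolerated flagged fraction before rejection.
#' @return a `beat_series` with corrected `rr`, `quality_flags` set and
#'   `n_corrected` recorded. Peak times are left untouched; corrected
#'   intervals live only in `rr`.
#' @export
correct_artifacts <- function(beats, tol = 0.25, max_flagged = 0.20) {
  stopifnot(inherits(beats, "beat_series"))
  if (!(tol > 0 && tol < 1)) stop("tol must be in (0, 1)")
  rr <- beats$rr
  n <- length(rr)
  # median of the 11 surrounding intervals (the interval itself excluded)
  ref <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - 5L); hi <- min(n, i + 5L)
    idx <- setdiff(lo:hi, i)
    stats::median(rr[idx])
  }, numeric(1))
  flag <- abs(rr - ref) / ref > tol
  if (mean(flag) > max_flagged)
    stop(sprintf("window unanalyzable: %.0f%% of intervals flagged", 100 * mean(flag)))
  out <- beats
  if (any(flag)) {
    good <- which(!flag)
    if (length(good) < 4L) stop("too few clean intervals to interpolate")
    t_mid <- (beats$peak_times[-1] + beats$peak_times[-(n + 1L)]) / 2
    f <- stats::splinefun(t_mid[good], rr[good], method = "natural")
    rr[flag] <- f(t_mid[flag])
    out$rr <- rr
  }
  out$quality_flags <- flag
  out$n_corrected <- sum(flag)
  out
}

#' Smoothness-priors detrending
#'
#' High-pass detrending by the smoothness-priors (regularised least squares)
#' method: with `D2` the second-difference operator, the trend is
#' `u = (I + lam^2 D2'D2)^{-1} y` and the detrended series is `y - u`.
#' Constants and linear ramps lie in the null space of `D2` and are removed
#' exactly; with `lam = 500` at 4 Hz the equivalent cutoff sits near 0.035 Hz,
#' below the LF bands of both populations.
#'
#' The solve uses a sparse Cholesky factorisation of the (banded, SPD)
#' system matrix rather than forming the dense inverse.
#'
#' @param y numeric vector or `uniform_series`, length >= 3, finite.
#' @param lam smoothing parameter (dimensionless), default 500.
#' @return same shape as `y`, detrended.
#' @export
detrend_smoothness_priors <- function(y, lam = 500) {
  if (inherits(y, "uniform_series")) {
    out <- y
    out$values <- detrend_smoothness_priors(y$values, lam)
    return(out)
  }
  y <- as.numeric(y)
  n <- length(y)
  if (n < 3L) stop("need at least 3 samples to detrend")
  if (!all(is.finite(y))) stop("non-finite input")
  if (lam <= 0) stop("lam must be > 0")
  D2 <- second_diff_matrix(n)
  A <- Matrix::Diagonal(n) + lam^2 * Matrix::crossprod(D2)
  trend <- as.numeric(Matrix::solve(A, y))
  y - trend
}

second_diff_matrix <- function(n) {
  i <- rep(seq_len(n - 2L), each = 3L)
  j <- as.vector(vapply(seq_len(n - 2L), function(k) k + 0:2, numeric(3)))
  Matrix::sparseMatrix(i = i, j = j, x = rep(c(1, -2, 1), n - 2L),
                       dims = c(n - 2L, n))
}

#' Resample an RR sequence onto a uniform 4 Hz grid
#'
#' Cubic-spline interpolation of beat-domain RR values (detrended or raw)
#' onto an evenly sampled grid spanning the beat times. Each interval is
#' timestamped at its closing beat.
#'
#' @param beats a `beat_series`.
#' @param rr_values values to interpolate; defaults to `beats$rr`. Pass the
#'   detrended sequence to obtain the standard RRi signal.
#' @param target_fs output rate in Hz, default 4.
#' @return a `uniform_series` labelled `"RRi"`.
#' @export
resample_rri <- function(beats, rr_values = beats$rr, target_fs = 4) {
  stopifnot(inherits(beats, "beat_series"))
  tt <- beats$peak_times[-1]
  span <- tt[length(tt)] - tt[1]
  if (span < 30) stop("segment shorter than 30 s cannot be resampled")
  if (span < 60) warning("segment shorter than 60 s; spectral metrics will be unreliable")
  grid <- seq(tt[1], tt[length(tt)], by = 1 / target_fs)
  f <- stats::splinefun(tt, rr_values, method = "natural")
  uniform_series(f(grid), fs = target_fs, t0 = grid[1], label = "RRi")
}

#' Preprocess an infant respiratory signal
#'
#' Fixed pipeline for monitor-acquired infant respiration: anti-alias
#' low-pass and downsample to 16 Hz, zero-phase 5th-order Butterworth
#' band-pass 0.05-2 Hz, subtraction of a centred 1.2 s running-median
#' baseline, resampling to 4 Hz, and z-scoring.
#'
#' @param raw a `uniform_series` at native rate >= 16 Hz.
#' @param target_fs output rate, default 4 Hz.
#' @return a `uniform_series` labelled `"RESP"`, mean 0 / sd 1.
#' @export
preprocess_infant_resp <- function(raw, target_fs = 4) {
  stopifnot(inherits(raw, "uniform_series"))
  if (raw$fs < 16) stop("native sampling rate below 16 Hz")
  if (stats::sd(raw$values) == 0) stop("flatline respiratory signal")
  # remove the mean first: a large DC offset would otherwise excite
  # zero-phase filter edge transients proportional to the offset
  x <- raw$values - mean(raw$values)
  fs <- raw$fs
  # anti-alias then interpolate onto the 16 Hz grid
  if (fs > 16) {
    bf <- signal::butter(8, (0.45 * 16) / (fs / 2), type = "low")
    x <- signal::filtfilt(bf, x)
    t_old <- series_times(raw)
    t_new <- seq(t_old[1], t_old[length(t_old)], by = 1 / 16)
    x <- stats::approx(t_old, x, xout = t_new)$y
    fs <- 16
    t0 <- t_new[1]
  } else t0 <- raw$t0
  # 5th-order band-pass applied as zero-phase high-pass + low-pass cascade;
  # the direct order-10 band-pass recursion is numerically unstable at the
  # very low relative band edge (0.05 Hz at 16 Hz)
  x <- signal::filtfilt(signal::butter(5, 0.05 / (fs / 2), "high"), x)
  x <- signal::filtfilt(signal::butter(5, 2 / (fs / 2), "low"), x)
  x <- x - running_median(x, round(1.2 * fs))
  # band limited to 2 Hz, the Nyquist of the target grid: decimate by spline
  t_cur <- t0 + (seq_along(x) - 1) / fs
  t_out <- seq(t_cur[1], t_cur[length(t_cur)], by = 1 / target_fs)
  x <- stats::spline(t_cur, x, xout = t_out)$y
  if (stats::sd(x) == 0) stop("flatline after filtering")
  x <- (x - mean(x)) / stats::sd(x)
  uniform_series(x, fs = target_fs, t0 = t_out[1], label = "RESP")
}

# centred running median with edge truncation
running_median <- function(x, k) {
  if (k %% 2L == 0L) k <- k + 1L
  n <- length(x)
  half <- (k - 1L) %/% 2L
  out <- stats::runmed(x, k, endrule = "keep")
  # recompute truncated-window medians at the edges
  for (i in seq_len(min(half, n))) {
    out[i] <- stats::median(x[1:min(n, i + half)])
    out[n - i + 1L] <- stats::median(x[max(1L, n - i + 1L - half):n])
  }
  out
}

#' Preprocess an adult recorded respiratory signal
#'
#' Adult analogue of [preprocess_infant_resp()]: zero-phase Butterworth
#' band-pass 0.05-2 Hz (high-pass + low-pass cascade), resampling to 4 Hz
#' and z-scoring. The short running-median baseline step is omitted: its
#' 1.2 s window matches one infant breath (~0.85 Hz) and cancels over a
#' cycle, but at adult rates (~0.25 Hz) it would track and distort the
#' waveform itself; the 0.05 Hz high-pass already removes baseline drift.
#'
#' @param raw a `uniform_series` at native rate >= 16 Hz.
#' @param target_fs output rate, default 4 Hz.
#' @return a `uniform_series` labelled `"RESP"`, mean 0 / sd 1.
#' @export
preprocess_adult_resp <- function(raw, target_fs = 4) {
  stopifnot(inherits(raw, "uniform_series"))
  if (raw$fs < 16) stop("native sampling rate below 16 Hz")
  if (stats::sd(raw$values) == 0) stop("flatline respiratory signal")
  x <- raw$values - mean(raw$values)
  fs <- raw$fs
  x <- signal::filtfilt(signal::butter(5, 0.05 / (fs / 2), "high"), x)
  x <- signal::filtfilt(signal::butter(5, 2 / (fs / 2), "low"), x)
  t_cur <- raw$t0 + (seq_along(x) - 1) / fs
  t_out <- seq(t_cur[1], t_cur[length(t_cur)], by = 1 / target_fs)
  x <- stats::spline(t_cur, x, xout = t_out)$y
  if (stats::sd(x) == 0) stop("flatline after filtering")
  x <- (x - mean(x)) / stats::sd(x)
  uniform_series(x, fs = target_fs, t0 = t_out[1], label = "RESP")
}

#' Z-score a uniform series
#' @param x a `uniform_series`.
#' @return the series scaled to mean 0, sd 1.
#' @export
series_zscore <- function(x) {
  stopifnot(inherits(x, "uniform_series"))
  s <- stats::sd(x$values)
  if (s == 0) stop("cannot z-score a constant series")
  x$values <- (x$values - mean(x$values)) / s
  x
}
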