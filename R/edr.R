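#' ECG band-pass filtering for the slope-range pipeline
#'
#' Zero-phase Butterworth filtering of a single-lead ECG: a high-pass at
#' `hp_cut` (default 0.8 Hz, order 12) removes baseline wander, a low-pass
#' at `lp_cut` (default 30 Hz, order 12) removes high-frequency noise.
#' Order-12 filters are applied as cascaded order-4 zero-phase sections for
#' numerical stability of the recursion at high sampling rates.
#'
#' @param ecg a `uniform_series` with `fs >= 100` Hz.
#' @param hp_cut,lp_cut cutoffs in Hz.
#' @return the filtered `uniform_series`.
#' @export
filter_ecg <- function(ecg, hp_cut = 0.8, lp_cut = 30) {
  stopifnot(inherits(ecg, "uniform_series"))
  if (ecg$fs < 100) stop("ECG sampling rate below 100 Hz")
  if (lp_cut >= ecg$fs / 2) stop("low-pass cutoff at or above Nyquist")
  x <- ecg$values
  for (k in 1:3) {
    x <- signal::filtfilt(signal::butter(4, hp_cut / (ecg$fs / 2), "high"), x)
    x <- signal::filtfilt(signal::butter(4, lp_cut / (ecg$fs / 2), "low"), x)
  }
  out <- ecg; out$values <- x
  out
}

#' R-peak detection
#'
#' Standard derivative-square-integrate detector: the squared central
#' derivative of the filtered ECG is smoothed with a 120 ms moving window;
#' local maxima of the envelope above an adaptive threshold, separated by a
#' refractory period (0.25 s adult, 0.18 s infant), are refined to the
#' nearest maximum of the ECG itself.
#'
#' @param ecg a filtered `uniform_series` (see [filter_ecg()]).
#' @param refractory minimum beat separation in seconds.
#' @param threshold_frac envelope threshold as a fraction of its 99th
#'   percentile (default 0.2).
#' @return strictly increasing peak times in seconds.
#' @export
detect_r_peaks <- function(ecg, refractory = 0.25, threshold_frac = 0.2) {
  stopifnot(inherits(ecg, "uniform_series"))
  x <- ecg$values
  fs <- ecg$fs
  n <- length(x)
  if (stats::sd(x) == 0) stop("flat ECG signal")
  d <- c(0, (x[3:n] - x[1:(n - 2)]) * fs / 2, 0)
  env <- stats::filter(d^2, rep(1 / round(0.12 * fs), round(0.12 * fs)),
                       sides = 2)
  env[is.na(env)] <- 0
  env <- as.numeric(env)
  thr <- threshold_frac * stats::quantile(env, 0.99)
  cand <- which(env > thr &
                  env >= c(-Inf, env[-n]) & env > c(env[-1], -Inf))
  if (length(cand) == 0L) stop("no R peaks found")
  # refractory: greedy keep-larger
  keep <- integer(0)
  for (i in cand) {
    if (length(keep) == 0L || (i - keep[length(keep)]) / fs >= refractory) {
      keep <- c(keep, i)
    } else if (env[i] > env[keep[length(keep)]]) {
      keep[length(keep)] <- i
    }
  }
  # refine to the local ECG maximum within +/- 50 ms
  half <- round(0.05 * fs)
  peaks <- vapply(keep, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))
  series_times(ecg)[peaks]
}

#' Beat-wise slope range of the QRS complex
#'
#' For each R peak, the slope range is the difference between the maximum
#' up-slope and the minimum down-slope of the filtered ECG within
#' `[peak - qrs_halfwidth, peak + qrs_halfwidth]` (central-difference
#' derivative). Respiratory modulation of QRS morphology makes this a
#' respiration surrogate. Beats whose window would run off the signal are
#' dropped with a warning.
#'
#' @param ecg filtered ECG `uniform_series`.
#' @param peaks R-peak times in seconds.
#' @param qrs_halfwidth half-width of the QRS window in seconds (default 0.05).
#' @return a list of class `beat_values`: `times`, `values`.
#' @export
slope_range_series <- function(ecg, peaks, qrs_halfwidth = 0.05) {
  stopifnot(inherits(ecg, "uniform_series"))
  x <- ecg$values
  fs <- ecg$fs
  n <- length(x)
  d <- c(NA, (x[3:n] - x[1:(n - 2)]) * fs / 2, NA)
  tt <- series_times(ecg)
  hw <- round(qrs_halfwidth * fs)
  idx <- round((peaks - ecg$t0) * fs) + 1L
  ok <- idx - hw >= 2L & idx + hw <= n - 1L
  if (any(!ok)) warning(sprintf("%d beat(s) at the signal edge dropped", sum(!ok)))
  idx <- idx[ok]
  vals <- vapply(idx, function(i) {
    w <- d[(i - hw):(i + hw)]
    max(w) - min(w)
  }, numeric(1))
  structure(list(times = tt[idx], values = vals), class = "beat_values")
}

#' Outlier correction of a beat-indexed series
#'
#' Values deviating from the 11-beat running median by more than
#' `n_mad` times the series' median absolute deviation are replaced by
#' that running median.
#'
#' @param edr a `beat_values` list with >= 10 beats.
#' @param n_mad deviation threshold in MADs (default 3).
#' @return the corrected `beat_values`, with `n_corrected` attached.
#' @export
correct_edr_outliers <- function(edr, n_mad = 3) {
  stopifnot(inherits(edr, "beat_values"))
  v <- edr$values
  if (length(v) < 10L) stop("need at least 10 beats")
  med <- running_median(v, 11L)
  s <- stats::mad(v)
  if (s == 0) return(edr)
  bad <- abs(v - med) > n_mad * s
  v[bad] <- med[bad]
  out <- edr
  out$values <- v
  out$n_corrected <- sum(bad)
  out
}

#' Resample a beat-indexed EDR series to a uniform grid
#'
#' Cubic-spline interpolation onto a 4 Hz grid spanning the beat times,
#' followed by z-scoring so the surrogate is commensurate with directly
#' recorded (z-scored) respiration.
#'
#' @param edr a `beat_values` list.
#' @param target_fs output rate in Hz (default 4).
#' @return a `uniform_series` labelled `"EDR"`, mean 0 / sd 1 (constant
#'   input is passed through un-scaled).
#' @export
edr_to_uniform <- function(edr, target_fs = 4) {
  stopifnot(inherits(edr, "beat_values"))
  tt <- edr$times
  grid <- seq(tt[1], tt[length(tt)], by = 1 / target_fs)
  f <- stats::splinefun(tt, edr$values, method = "natural")
  v <- f(grid)
  if (stats::sd(v) > 0) v <- (v - mean(v)) / stats::sd(v)
  uniform_series(v, fs = target_fs, t0 = grid[1], label = "EDR")
}

#' Full ECG-derived respiration pipeline
#'
#' Convenience wrapper: filter, detect peaks, slope range, outlier
#' correction, uniform resampling. Returns both the respiration surrogate
#' and the detected peak times (reused for the RR branch).
#'
#' @param ecg raw single-lead ECG `uniform_series`.
#' @param refractory R-peak refractory period in seconds.
#' @param qrs_halfwidth QRS window half-width in seconds.
#' @return a list with `edr` (4 Hz `uniform_series`) and `peaks` (seconds).
#' @export
ecg_derived_respiration <- function(ecg, refractory = 0.25, qrs_halfwidth = 0.05) {
  f <- filter_ecg(ecg)
  peaks <- detect_r_peaks(f, refractory = refractory)
  sr <- slope_range_series(f, peaks, qrs_halfwidth = qrs_halfwidth)
  sr <- correct_edr_outliers(sr)
  list(edr = edr_to_uniform(sr), peaks = peaks)
}
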