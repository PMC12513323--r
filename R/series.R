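#' Uniformly sampled signal
#'
#' The common container after preprocessing: a numeric vector sampled at a
#' fixed rate, with a start time and a label identifying what it holds
#' (`"RRi"`, `"RESP"`, `"EDR"`, or `"ECG"`).
#'
#' @param values numeric vector, finite, length >= 2.
#' @param fs sampling rate in Hz (> 0).
#' @param t0 time of the first sample in seconds (default 0).
#' @param label one of `"RRi"`, `"RESP"`, `"EDR"`, `"ECG"` or another short tag.
#' @return an object of class `uniform_series`.
#' @export
uniform_series <- function(values, fs, t0 = 0, label = "signal") {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("uniform_series needs at least 2 samples")
  if (!all(is.finite(values))) stop("uniform_series values must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  structure(list(values = values, fs = fs, t0 = t0, label = label),
            class = "uniform_series")
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<uniform_series '%s'>  %d samples @ %.6g Hz, %.1f s, t0 = %.3f s\n",
              x$label, length(x$values), x$fs, length(x$values) / x$fs, x$t0))
  invisible(x)
}

#' @export
length.uniform_series <- function(x) length(x$values)

#' Sample times of a uniform series
#' @param x a `uniform_series`.
#' @return numeric vector of sample times in seconds.
#' @export
series_times <- function(x) {
  stopifnot(inherits(x, "uniform_series"))
  x$t0 + (seq_along(x$values) - 1) / x$fs
}

#' Crop a uniform series to a time interval
#' @param x a `uniform_series`.
#' @param start,end interval bounds in seconds (same clock as `t0`).
#' @return a `uniform_series` covering `[start, end]`.
#' @export
series_crop <- function(x, start, end) {
  tt <- series_times(x)
  keep <- tt >= start - 1e-9 & tt <= end + 1e-9
  if (sum(keep) < 2L) stop("crop interval contains fewer than 2 samples")
  uniform_series(x$values[keep], x$fs, t0 = tt[which(keep)[1]], label = x$label)
}

#' Beat series: R-peak times and RR intervals
#'
#' @param peak_times strictly increasing R-peak occurrence times in seconds.
#' @return an object of class `beat_series` with fields `peak_times`, `rr`
#'   (first differences, seconds) and `quality_flags` (per-interval logical,
#'   `TRUE` where an interval was flagged/corrected).
#' @export
beat_series <- function(peak_times) {
  peak_times <- as.numeric(peak_times)
  if (length(peak_times) < 3L) stop("need at least 3 R-peaks")
  d <- diff(peak_times)
  bad <- which(d <= 0)
  if (length(bad) > 0L)
    stop(sprintf("peak times not strictly increasing at index %d", bad[1] + 1L))
  structure(list(peak_times = peak_times, rr = d,
                 quality_flags = logical(length(d)), n_corrected = 0L),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series>  %d beats over %.1f s, mean RR %.3f s (%.0f bpm), %d corrected\n",
              length(x$peak_times), diff(range(x$peak_times)), mean(x$rr),
              60 / mean(x$rr), x$n_corrected))
  invisible(x)
}

#' Read a one-column peak-time file / two-column signal CSV
#'
#' Plain-text readers for the package's external interchange formats: R-peak
#' times as a single column of seconds, and sampled signals as either a
#' two-column `t,value` CSV or a one-column value file with the rate given.
#'
#' @param path file path.
#' @param fs sampling rate in Hz; required for one-column signal files.
#' @param label signal label for the returned series.
#' @return `read_peak_times`: numeric vector; `read_signal_csv`: a
#'   `uniform_series`.
#' @export
read_peak_times <- function(path) {
  x <- utils::read.table(path, header = FALSE)[[1]]
  as.numeric(x)
}

#' @rdname read_peak_times
#' @export
read_signal_csv <- function(path, fs = NULL, label = "signal") {
  d <- utils::read.csv(path, header = TRUE)
  if (ncol(d) >= 2L) {
    tt <- d[[1]]
    dt <- diff(tt)
    fs_est <- 1 / stats::median(dt)
    uniform_series(d[[2]], fs = fs_est, t0 = tt[1], label = label)
  } else {
    if (is.null(fs)) stop("one-column signal file needs an explicit fs")
    uniform_series(d[[1]], fs = fs, label = label)
  }
}

#' Write a uniform series as a t,value CSV
#' @param x a `uniform_series`.
#' @param path output path.
#' @export
write_signal_csv <- function(x, path) {
  utils::write.csv(data.frame(t = series_times(x), value = x$values),
                   path, row.names = FALSE)
  invisible(path)
}
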