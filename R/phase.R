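#' Analytic-signal instantaneous phase
#'
#' Band-passes the series to the population's respiratory band (zero-phase
#' 4th-order Butterworth) and takes the phase of the analytic signal
#' (FFT half-spectrum construction). Phase of a broadband series is
#' ill-defined, hence the band-limiting. The first and last 5 s are flagged
#' for exclusion to suppress analytic-signal boundary artifacts.
#'
#' @param x a `uniform_series`.
#' @param band Hz interval for the band-pass, e.g. `band_scheme("adult")$resp_band`.
#' @param edge_s seconds flagged at each end (default 5).
#' @return a list of class `phase_series`: `phi` (radians in (-pi, pi]),
#'   `fs`, and `keep` (logical, FALSE on flagged edges).
#' @export
instantaneous_phase <- function(x, band, edge_s = 5) {
  stopifnot(inherits(x, "uniform_series"))
  if (band[2] >= x$fs / 2) stop("band upper edge at or above Nyquist")
  if (length(x$values) < 8 * x$fs) stop("series shorter than 8 s")
  bf <- signal::butter(4, band / (x$fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x$values - mean(x$values))
  phi <- Arg(analytic_signal(xf))
  n <- length(phi)
  ne <- min(round(edge_s * x$fs), floor((n - 1) / 2))
  keep <- rep(TRUE, n)
  if (ne > 0) keep[c(seq_len(ne), (n - ne + 1L):n)] <- FALSE
  structure(list(phi = phi, fs = x$fs, keep = keep), class = "phase_series")
}

# analytic signal via half-spectrum doubling
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Mean phase coherence
#'
#' Circular mean resultant length of the instantaneous phase difference:
#' `MPC = |mean(exp(i (phi_x - phi_y)))|`, in [0, 1]; 1 means perfect 1:1
#' phase locking. Samples flagged by either phase series (edges) are
#' excluded.
#'
#' @param px_,py_ `phase_series` of equal length.
#' @return MPC in [0, 1].
#' @export
mpc <- function(px_, py_) {
  stopifnot(inherits(px_, "phase_series"), inherits(py_, "phase_series"))
  if (length(px_$phi) != length(py_$phi)) stop("phase series length mismatch")
  keep <- px_$keep & py_$keep
  d <- px_$phi[keep] - py_$phi[keep]
  Mod(mean(exp(1i * d)))
}
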