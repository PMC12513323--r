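#' Age-specific HRV frequency bands
#'
#' Band edges differ between populations because infant respiration
#' (~0.7-1 Hz) lies far above the adult high-frequency band.
#'
#' @param population `"infant"` or `"adult"`.
#' @return a list with elements `population`, `lf` and `hf` (Hz intervals),
#'   plus `resp_band`, the band used for phase extraction and respiratory
#'   cycle detection.
#' @export
band_scheme <- function(population = c("adult", "infant")) {
  population <- match.arg(population)
  if (population == "adult")
    list(population = "adult", lf = c(0.04, 0.15), hf = c(0.15, 0.40),
         resp_band = c(0.10, 0.50))
  else
    list(population = "infant", lf = c(0.02, 0.20), hf = c(0.20, 1.50),
         resp_band = c(0.30, 1.50))
}

#' Welch power spectral density
#'
#' Segment-averaged one-sided periodogram: Hamming-tapered segments of
#' `seg_len` seconds with fractional `overlap`, each mean-removed before the
#' FFT. Scaling satisfies Parseval (`sum(psd) * df ~ var(x)`) for broadband
#' inputs.
#'
#' @param x a `uniform_series` or numeric vector.
#' @param fs sampling rate; taken from `x` when it is a series.
#' @param seg_len segment length in seconds (default 60).
#' @param overlap fractional overlap in [0, 1) (default 0.5).
#' @param demean remove the series mean before segmenting (default TRUE).
#' @return a list with `freqs` (Hz), `psd` (power per Hz), `n_segments`, `df`.
#' @export
welch_psd <- function(x, fs = NULL, seg_len = 60, overlap = 0.5, demean = TRUE) {
  cs <- welch_cross(x, x, fs = fs, seg_len = seg_len, overlap = overlap,
                    demean = demean)
  list(freqs = cs$freqs, psd = Re(cs$pxy), n_segments = cs$n_segments,
       df = cs$df)
}

# shared Welch engine: averaged (cross-)spectral density of x and y
welch_cross <- function(x, y, fs = NULL, seg_len = 60, overlap = 0.5,
                        demean = TRUE) {
  if (inherits(x, "uniform_series")) { fs <- x$fs; x <- x$values }
  if (inherits(y, "uniform_series")) y <- y$values
  if (is.null(fs)) stop("fs required for plain numeric input")
  if (length(x) != length(y)) stop("series lengths differ")
  nseg <- round(seg_len * fs)
  if (length(x) < nseg) stop("series shorter than one Welch segment")
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  if (demean) { x <- x - mean(x); y <- y - mean(y) }
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))
  scale <- fs * sum(w^2)
  nf <- nseg %/% 2L + 1L
  acc <- complex(nf)
  for (s in starts) {
    xs <- x[s:(s + nseg - 1L)]; ys <- y[s:(s + nseg - 1L)]
    X <- stats::fft(w * (xs - mean(xs)))[1:nf]
    Y <- stats::fft(w * (ys - mean(ys)))[1:nf]
    acc <- acc + X * Conj(Y)
  }
  pxy <- acc / (length(starts) * scale)
  # one-sided: double everything except DC (and Nyquist when nseg is even)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (nseg %% 2L == 0L) dbl[nf] <- 1
  list(freqs = (seq_len(nf) - 1) * fs / nseg, pxy = pxy * dbl,
       n_segments = length(starts), df = fs / nseg)
}

#' Band-integrated spectral metrics
#'
#' Trapezoidal integration of the PSD over the LF and HF bands of a
#' [band_scheme()], with the LF/HF ratio.
#'
#' @param psd_result output of [welch_psd()].
#' @param scheme a [band_scheme()].
#' @return a list with `hf_power`, `lf_power`, `lf_hf_ratio` (NA when HF
#'   power is zero), `freqs`, `psd` and the scheme.
#' @export
band_metrics <- function(psd_result, scheme) {
  lf <- band_power(psd_result$freqs, psd_result$psd, scheme$lf)
  hf <- band_power(psd_result$freqs, psd_result$psd, scheme$hf)
  list(hf_power = hf, lf_power = lf,
       lf_hf_ratio = if (hf > 0) lf / hf else NA_real_,
       freqs = psd_result$freqs, psd = psd_result$psd, scheme = scheme)
}

#' Trapezoidal band power
#' @param freqs,psd spectral estimate.
#' @param band Hz interval `c(lo, hi)`.
#' @return integrated power in the band.
#' @export
band_power <- function(freqs, psd, band) {
  keep <- freqs >= band[1] & freqs <= band[2]
  if (sum(keep) < 2L) return(0)
  f <- freqs[keep]; p <- psd[keep]
  sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
}

#' Mean magnitude-squared coherence over [0, 2] Hz
#'
#' Welch-averaged magnitude-squared coherence
#' `C_xy(f) = |P_xy(f)|^2 / (P_xx(f) P_yy(f))`, averaged across the
#' frequency range 0-2 Hz. At least 4 segments are required: the
#' single-segment estimate is identically 1 and carries no information.
#'
#' @param x,y `uniform_series` of equal length and rate (4 Hz pipeline grid).
#' @param seg_len,overlap Welch parameters as in [welch_psd()].
#' @param band averaging range in Hz, default `c(0, 2)`.
#' @return a list with `mean_msc`, per-frequency `msc`, `freqs`,
#'   `n_segments` and `band`.
#' @export
mean_msc <- function(x, y, seg_len = 60, overlap = 0.5, band = c(0, 2)) {
  cxy <- welch_cross(x, y, seg_len = seg_len, overlap = overlap)
  cxx <- welch_cross(x, x, seg_len = seg_len, overlap = overlap)
  cyy <- welch_cross(y, y, seg_len = seg_len, overlap = overlap)
  if (cxy$n_segments < 4L)
    stop("magnitude-squared coherence needs at least 4 Welch segments")
  denom <- Re(cxx$pxy) * Re(cyy$pxy)
  msc <- ifelse(denom > 0, Mod(cxy$pxy)^2 / denom, 0)
  msc <- pmin(pmax(msc, 0), 1)
  keep <- cxy$freqs >= band[1] & cxy$freqs <= band[2]
  list(mean_msc = mean(msc[keep]), msc = msc, freqs = cxy$freqs,
       n_segments = cxy$n_segments, band = band)
}
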