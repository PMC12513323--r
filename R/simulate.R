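#' Synthetic subject configuration
#'
#' Physiological parameters for one simulated subject. Population defaults
#' reflect the two study groups: preterm infants (HR 140-160 bpm,
#' respiration 0.7-1.0 Hz — above the adult HF band) and adults (HR 60-80
#' bpm, respiration 0.2-0.3 Hz). `rsa_gain` is the respiration-to-RR
#' modulation depth (fraction of the mean heart period), `lf_gain` the
#' depth of an independent 0.095 Hz oscillation, `reverse_gain` the
#' RR-to-respiration leakage, `noise_sd` the sd of the broadband modulation
#' noise (white on the 8 Hz simulation grid; the IPFM integrator turns it
#' into beat-to-beat RR variability). Default gains put the LF oscillation
#' above the respiratory modulation, matching the LF/HF balance reported
#' for both populations (adult LF/HF of order 1-3, infant of order 10).
#'
#' @param population `"infant"` or `"adult"`.
#' @param hr_mean mean heart rate in bpm.
#' @param resp_freq mean respiratory frequency in Hz.
#' @param rsa_gain,lf_gain,reverse_gain,noise_sd nonnegative gains.
#' @param seed integer RNG seed for this subject.
#' @return a list of class `subject_config`.
#' @export
subject_config <- function(population = c("adult", "infant"),
                           hr_mean = NULL, resp_freq = NULL,
                           rsa_gain = NULL, lf_gain = NULL,
                           reverse_gain = 0, noise_sd = 0.03, seed = 1L) {
  population <- match.arg(population)
  def <- if (population == "adult")
    list(hr_mean = 70, resp_freq = 0.25, rsa_gain = 0.04, lf_gain = 0.06)
  else
    list(hr_mean = 150, resp_freq = 0.85, rsa_gain = 0.01, lf_gain = 0.03)
  cfg <- list(population = population,
              hr_mean = if (is.null(hr_mean)) def$hr_mean else hr_mean,
              resp_freq = if (is.null(resp_freq)) def$resp_freq else resp_freq,
              rsa_gain = if (is.null(rsa_gain)) def$rsa_gain else rsa_gain,
              lf_gain = if (is.null(lf_gain)) def$lf_gain else lf_gain,
              reverse_gain = reverse_gain, noise_sd = noise_sd,
              seed = as.integer(seed))
  if (any(c(cfg$rsa_gain, cfg$lf_gain, cfg$reverse_gain, cfg$noise_sd) < 0))
    stop("gains must be nonnegative")
  class(cfg) <- "subject_config"
  cfg
}

#' Protocol configuration
#'
#' Durations of the three contiguous protocol segments and per-condition
#' multipliers applied to the subject's gains. Defaults: 180 s pre, 360 s
#' stimulus, 180 s post, all multipliers 1 (exchangeable conditions —
#' a true null).
#'
#' @param pre_dur,music_dur,post_dur segment durations in seconds.
#' @param condition_effects named list `pre`/`music`/`post`, each a named
#'   numeric vector with any of `rsa`, `lf`, `rev` multipliers.
#' @return a list of class `protocol_config`.
#' @export
protocol_config <- function(pre_dur = 180, music_dur = 360, post_dur = 180,
                            condition_effects = NULL) {
  if (pre_dur < 180 || post_dur < 180)
    stop("pre and post segments must each last at least 180 s")
  eff <- list(pre = c(rsa = 1, lf = 1, rev = 1),
              music = c(rsa = 1, lf = 1, rev = 1),
              post = c(rsa = 1, lf = 1, rev = 1))
  for (cond in names(condition_effects))
    eff[[cond]][names(condition_effects[[cond]])] <- condition_effects[[cond]]
  structure(list(pre_dur = pre_dur, music_dur = music_dur,
                 post_dur = post_dur, condition_effects = eff),
            class = "protocol_config")
}

# evaluate an expression with a private RNG stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

SIM_FS <- 8  # internal simulation grid, Hz

#' Simulate a respiratory signal
#'
#' `r(t) = sin(phi(t))` with instantaneous frequency `resp_freq` modulated
#' by a bounded random walk (5% of the mean rate per minute, clipped at
#' +/-20%), plus white observation noise. With `reverse_gain > 0` a
#' low-frequency cardiac-fluctuation term (the same one that drives the
#' RR series) leaks additively into the respiration. Sampled at 8 Hz.
#'
#' The clean oscillation, the cardiac-fluctuation trace and the drift are
#' attached as attribute `"truth"` so recovery tests can read injected
#' effects back.
#'
#' @param cfg a [subject_config()].
#' @param dur duration in seconds (>= 60).
#' @param lf_mult,rev_mult optional per-sample multiplier traces
#'   (length `dur * 8`) applied to the subject gains (condition effects).
#' @return a `uniform_series` labelled `"RESP"` at 8 Hz.
#' @export
simulate_respiration <- function(cfg, dur, lf_mult = 1, rev_mult = 1) {
  stopifnot(inherits(cfg, "subject_config"))
  if (dur < 60) stop("duration must be at least 60 s")
  with_seed(cfg$seed, {
    n <- round(dur * SIM_FS)
    tt <- (seq_len(n) - 1) / SIM_FS
    step_sd <- 0.05 / sqrt(60 * SIM_FS)
    drift <- cumsum(stats::rnorm(n, 0, step_sd))
    drift <- pmin(pmax(drift, -0.2), 0.2)
    freq <- cfg$resp_freq * (1 + drift)
    phi <- 2 * pi * cumsum(freq) / SIM_FS
    r_clean <- sin(phi)
    theta <- stats::runif(1, 0, 2 * pi)
    lf <- sin(2 * pi * 0.095 * tt + theta)
    eps <- modulation_noise(n, cfg$noise_sd)
    card <- rep(lf_mult, length.out = n) * cfg$lf_gain * lf + eps
    leak <- slow_component(card)
    rev_term <- rep(rev_mult, length.out = n) * cfg$reverse_gain *
      (leak / max(stats::sd(leak), 1e-12))
    # respiration-channel disturbance is modelled as in-band waveform
    # irregularity (white noise band-passed to 0.15-1.5 Hz, spanning both
    # populations' breathing ranges): out-of-band sensor noise would be
    # removed by the preprocessing band-pass anyway, and low-frequency
    # noise would masquerade as cardiac-band structure
    obs_noise <- signal::filtfilt(
      signal::butter(2, c(0.15, 1.5) / (SIM_FS / 2), "pass"),
      stats::rnorm(n))
    obs_noise <- obs_noise / max(stats::sd(obs_noise), 1e-12) * cfg$noise_sd
    obs <- r_clean + rev_term + obs_noise
    out <- uniform_series(obs, fs = SIM_FS, label = "RESP")
    attr(out, "truth") <- list(r_clean = r_clean, cardiac = card,
                               lf = lf, drift = drift, theta = theta)
    out
  })
}

# residual autonomic RR variability: Gaussian noise band-limited to the
# low-frequency range (zero-phase 4th-order low-pass at 0.1 Hz), rescaled to
# the requested sd. Keeping the noise strictly below every respiratory band
# (slowest simulated breather: 0.2 Hz, attenuated ~256x) means a zero-RSA
# subject carries no RR power at the breathing frequency, which is what
# "uncoupled" should mean for the coupling metrics.
modulation_noise <- function(n, sd, cutoff = 0.1) {
  if (sd == 0) return(numeric(n))
  e <- signal::filtfilt(signal::butter(4, cutoff / (SIM_FS / 2), "low"),
                        stats::rnorm(n))
  e / max(stats::sd(e), 1e-12) * sd
}

# zero-phase low-pass used for the reverse (RR -> respiration) leak and
# for the slow respiration observation noise
slow_component <- function(x, fs = SIM_FS, cutoff = 0.5) {
  if (stats::sd(x) == 0) return(x)
  signal::filtfilt(signal::butter(2, cutoff / (fs / 2), "low"), x)
}

#' Simulate R-peak times by integral pulse frequency modulation
#'
#' The instantaneous heart period is
#' `T(t) = 60/hr_mean * (1 + rsa_gain * r(t) + cardiac(t))`, where `r(t)`
#' is the clean respiratory oscillation and `cardiac(t)` the LF + noise
#' fluctuation generated with the respiration. The IPFM integrator emits
#' a beat each time the integral of `1/T(t)` crosses an integer (linear
#' interpolation of the crossing time). `T(t)` is clipped below at 0.25 s.
#'
#' @param cfg a [subject_config()].
#' @param resp a respiration series from [simulate_respiration()] (its
#'   `"truth"` attribute supplies `r_clean` and `cardiac`).
#' @param rsa_mult optional per-sample multiplier trace on `rsa_gain`.
#' @return numeric vector of beat times in seconds (relative to `resp$t0`).
#' @export
simulate_beats <- function(cfg, resp, rsa_mult = 1) {
  stopifnot(inherits(cfg, "subject_config"), inherits(resp, "uniform_series"))
  truth <- attr(resp, "truth")
  if (is.null(truth)) stop("resp must carry its simulation ground truth")
  n <- length(resp$values)
  mod <- 1 + rep(rsa_mult, length.out = n) * cfg$rsa_gain * truth$r_clean +
    truth$cardiac
  period <- pmax(60 / cfg$hr_mean * mod, 0.25)
  if (any(mod <= 0)) stop("modulation drives the heart period nonpositive")
  rate <- 1 / period
  # trapezoidal cumulative integral of the instantaneous rate
  dt <- 1 / resp$fs
  integ <- c(0, cumsum((rate[-1] + rate[-n]) / 2 * dt))
  n_beats <- floor(integ[n])
  if (n_beats < 3) stop("too few beats generated")
  targets <- seq_len(n_beats)
  idx <- pmin(findInterval(targets, integ), n - 1L)
  frac <- (targets - integ[idx]) / (integ[idx + 1L] - integ[idx])
  unname((idx - 1L + frac) * dt + resp$t0)
}

#' Simulate a single-lead ECG from beat times
#'
#' Places a stereotyped QRS template (Gaussian R wave with small Q and S
#' deflections) at each beat, with its amplitude modulated by
#' `1 + mod_depth * r(t)` where `r(t)` is the clean respiratory
#' oscillation, plus sinusoidal baseline wander and white noise at the
#' requested SNR. Morphology is deliberately minimal: just enough for
#' R-peak detection and the slope-range respiration surrogate.
#'
#' @param peak_times beat times in seconds.
#' @param resp respiration series carrying its `"truth"` attribute.
#' @param cfg a [subject_config()] (used for the RNG seed).
#' @param fs output sampling rate in Hz (default 500).
#' @param mod_depth respiratory amplitude-modulation depth (default 0.1).
#' @param snr_db additive-noise SNR in dB (default 20).
#' @return a `uniform_series` labelled `"ECG"`.
#' @export
simulate_ecg <- function(peak_times, resp, cfg, fs = 500, mod_depth = 0.1,
                         snr_db = 20) {
  truth <- attr(resp, "truth")
  if (is.null(truth)) stop("resp must carry its simulation ground truth")
  with_seed(cfg$seed + 7L, {
    dur <- max(peak_times) + 0.5
    n <- round(dur * fs)
    tt <- (seq_len(n) - 1) / fs
    ecg <- numeric(n)
    r_at <- stats::approx(series_times(resp), truth$r_clean, xout = peak_times,
                          rule = 2)$y
    gauss <- function(t, mu, s) exp(-((t - mu)^2) / (2 * s^2))
    for (b in seq_along(peak_times)) {
      amp <- 1 + mod_depth * r_at[b]
      centre <- peak_times[b]
      lo <- max(1L, floor((centre - 0.08) * fs) + 1L)
      hi <- min(n, ceiling((centre + 0.08) * fs) + 1L)
      tw <- tt[lo:hi]
      ecg[lo:hi] <- ecg[lo:hi] + amp * (gauss(tw, centre, 0.012) -
        0.15 * gauss(tw, centre - 0.040, 0.010) -
        0.20 * gauss(tw, centre + 0.035, 0.012))
    }
    wander <- 0.15 * sin(2 * pi * 0.2 * tt + stats::runif(1, 0, 2 * pi))
    noise_sd <- sqrt(mean(ecg^2)) / 10^(snr_db / 20)
    uniform_series(ecg + wander + stats::rnorm(n, 0, noise_sd),
                   fs = fs, label = "ECG")
  })
}

#' Generate one synthetic subject recording
#'
#' Simulates the three contiguous protocol segments (pre / music / post)
#' with the protocol's condition multipliers applied as per-sample gain
#' traces, then runs the IPFM beat generator over the whole recording.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [subject_config()].
#' @param protocol a [protocol_config()].
#' @param with_ecg also synthesise a 500 Hz ECG (default FALSE).
#' @param resp_out_fs output rate of the respiration channel (default 32 Hz,
#'   spline-resampled from the 8 Hz simulation grid).
#' @return a list of class `subject_recording`: `peak_times`, `resp`
#'   (raw-channel `uniform_series`), `segments` (data.frame condition /
#'   start / end), `truth` (injected parameters incl. clean respiration),
#'   `cfg`, and optionally `ecg`.
#' @export
generate_subject <- function(cfg, protocol = protocol_config(),
                             with_ecg = FALSE, resp_out_fs = 32) {
  stopifnot(inherits(cfg, "subject_config"), inherits(protocol, "protocol_config"))
  durs <- c(pre = protocol$pre_dur, music = protocol$music_dur,
            post = protocol$post_dur)
  total <- sum(durs)
  npts <- round(durs * SIM_FS)
  trace <- function(field) rep(vapply(protocol$condition_effects, `[[`,
                                      numeric(1), field), times = npts)
  rsa_t <- trace("rsa"); lf_t <- trace("lf"); rev_t <- trace("rev")
  resp <- simulate_respiration(cfg, total, lf_mult = lf_t, rev_mult = rev_t)
  peaks <- simulate_beats(cfg, resp, rsa_mult = rsa_t)
  bounds <- cumsum(c(0, durs))
  segments <- data.frame(condition = names(durs), start = bounds[1:3],
                         end = bounds[2:4], row.names = NULL)
  # raw channel at the monitor-like rate
  t8 <- series_times(resp)
  t_out <- seq(0, total - 1 / resp_out_fs, by = 1 / resp_out_fs)
  resp_raw <- uniform_series(stats::spline(t8, resp$values, xout = t_out)$y,
                             fs = resp_out_fs, label = "RESP")
  rec <- list(peak_times = peaks, resp = resp_raw, segments = segments,
              truth = list(cfg = cfg, protocol = protocol,
                           r_clean = attr(resp, "truth")$r_clean,
                           sim_fs = SIM_FS),
              cfg = cfg)
  if (with_ecg) rec$ecg <- simulate_ecg(peaks, resp, cfg)
  class(rec) <- "subject_recording"
  rec
}

#' @export
print.subject_recording <- function(x, ...) {
  cat(sprintf("<subject_recording '%s'>  %d beats, %.0f s, resp %.2f Hz, rsa_gain %.3f\n",
              x$cfg$population, length(x$peak_times),
              max(x$segments$end), x$cfg$resp_freq, x$cfg$rsa_gain))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Draws per-subject physiology uniformly from the population ranges
#' (infants: HR 140-160 bpm, respiration 0.7-1.0 Hz; adults: HR 60-80 bpm,
#' respiration 0.2-0.3 Hz), assigns each subject a private seed derived
#' from the cohort seed, and simulates each recording. The ground-truth
#' manifest suffices to recompute every injected effect.
#'
#' @param n number of subjects (>= 2).
#' @param population `"infant"` or `"adult"`.
#' @param protocol a [protocol_config()].
#' @param seed cohort-level seed.
#' @param overrides named list of `subject_config` fields fixed for all
#'   subjects (e.g. `list(rsa_gain = 0, lf_gain = 0.03)`).
#' @param with_ecg simulate ECG channels too.
#' @return a list of class `cohort`: `recordings` (list) and `manifest`
#'   (data.frame of per-subject ground truth).
#' @export
generate_cohort <- function(n, population = c("adult", "infant"),
                            protocol = protocol_config(), seed = 1L,
                            overrides = list(), with_ecg = FALSE) {
  population <- match.arg(population)
  if (n < 2L) stop("need at least 2 subjects")
  rng <- if (population == "adult")
    list(hr = c(60, 80), rf = c(0.2, 0.3))
  else
    list(hr = c(140, 160), rf = c(0.7, 1.0))
  with_seed(seed, {
    hr <- stats::runif(n, rng$hr[1], rng$hr[2])
    rf <- stats::runif(n, rng$rf[1], rng$rf[2])
    seeds <- sample.int(.Machine$integer.max %/% 2L, n)
  })
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    args <- c(list(population = population, hr_mean = hr[i], resp_freq = rf[i],
                   seed = seeds[i]), overrides)
    args <- args[!duplicated(names(args))]
    # explicit overrides win over drawn values
    for (f in intersect(names(overrides), c("hr_mean", "resp_freq")))
      args[[f]] <- overrides[[f]]
    cfg <- do.call(subject_config, args)
    recs[[i]] <- generate_subject(cfg, protocol, with_ecg = with_ecg)
  }
  manifest <- do.call(rbind, lapply(seq_len(n), function(i) {
    cfg <- recs[[i]]$cfg
    data.frame(subject = i, population = cfg$population, hr_mean = cfg$hr_mean,
               resp_freq = cfg$resp_freq, rsa_gain = cfg$rsa_gain,
               lf_gain = cfg$lf_gain, reverse_gain = cfg$reverse_gain,
               noise_sd = cfg$noise_sd, seed = cfg$seed)
  }))
  structure(list(recordings = recs, manifest = manifest,
                 population = population, protocol = protocol, seed = seed),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort>  %d %s subjects, seed %d\n",
              length(x$recordings), x$population, x$seed))
  invisible(x)
}

#' Write a cohort to disk in the pipeline's interchange formats
#'
#' One directory per subject with `peaks.txt` (one column, seconds) and
#' `resp.csv` (t,value), plus `manifest.csv` of ground truth at the root.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$recordings)) {
    sd_ <- file.path(dir, sprintf("subject_%02d", i))
    dir.create(sd_, showWarnings = FALSE)
    rec <- cohort$recordings[[i]]
    utils::write.table(rec$peak_times, file.path(sd_, "peaks.txt"),
                       row.names = FALSE, col.names = FALSE)
    write_signal_csv(rec$resp, file.path(sd_, "resp.csv"))
  }
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}
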