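#' Analysis windows for a protocol recording
#'
#' Five 3-minute windows: the last 180 s of the pre segment, three
#' 180 s windows tiling the stimulus with 50% overlap (offsets 0,
#' `(music_dur - 180)/2`, `music_dur - 180`; i.e. 0/90/180 s for the
#' default 360 s stimulus), and the first 180 s of the post segment.
#' Segments too short for a window drop their condition with a warning.
#'
#' @param recording a `subject_recording` (or any list with a `segments`
#'   data.frame of condition/start/end rows).
#' @param win_dur window length in seconds (default 180).
#' @return a data.frame with columns `condition`, `start`, `dur`,
#'   `music_slot` (NA outside the stimulus).
#' @export
segment_windows <- function(recording, win_dur = 180) {
  seg <- recording$segments
  rows <- list()
  one <- function(cond) seg[seg$condition == cond, , drop = FALSE]
  pre <- one("pre")
  if (nrow(pre) && pre$end - pre$start >= win_dur) {
    rows[[length(rows) + 1L]] <- data.frame(condition = "pre",
      start = pre$end - win_dur, dur = win_dur, music_slot = NA_integer_)
  } else warning("pre segment too short; condition dropped")
  mus <- one("music")
  if (nrow(mus) && mus$end - mus$start >= win_dur) {
    mdur <- mus$end - mus$start
    offs <- unique(c(0, (mdur - win_dur) / 2, mdur - win_dur))
    rows[[length(rows) + 1L]] <- data.frame(condition = "music",
      start = mus$start + offs, dur = win_dur,
      music_slot = seq_along(offs))
  } else warning("music segment too short; condition dropped")
  post <- one("post")
  if (nrow(post) && post$end - post$start >= win_dur) {
    rows[[length(rows) + 1L]] <- data.frame(condition = "post",
      start = post$start, dur = win_dur, music_slot = NA_integer_)
  } else warning("post segment too short; condition dropped")
  do.call(rbind, rows)
}

#' Preprocess one analysis window of a recording
#'
#' Extracts the window's beats and respiration and runs the standard
#' preprocessing: artifact-corrected RR intervals, smoothness-priors
#' detrending in the beat domain (lambda = 500), 4 Hz spline resampling
#' (detrended branch `rri` and non-detrended branch `rri_raw` for the
#' phase-rectified averaging), and the respiration path (recorded channel
#' through the band-pass/median-baseline pipeline, or the slope-range ECG
#' surrogate when only ECG is available). Respiration is interpolated onto
#' the RRi time grid so all series share samples.
#'
#' @param recording a `subject_recording` or compatible list
#'   (`peak_times`, and `resp` and/or `ecg`).
#' @param start,dur window start and length in seconds.
#' @param lam detrending smoothing parameter.
#' @param population `"infant"` or `"adult"`, selecting the respiration
#'   preprocessing path; defaults to the recording's own population.
#' @return a list with `rri`, `rri_raw`, `resp` (all 4 Hz
#'   `uniform_series` of equal length) and `n_corrected`.
#' @export
prepare_window <- function(recording, start, dur = 180, lam = 500,
                           population = NULL) {
  if (is.null(population))
    population <- if (!is.null(recording$cfg)) recording$cfg$population
    else "adult"
  end <- start + dur
  pk <- recording$peak_times
  pk <- pk[pk >= start - 2 & pk <= end + 2]
  beats <- rr_from_peaks(pk)
  beats <- correct_artifacts(beats)
  rr_det <- detrend_smoothness_priors(beats$rr, lam = lam)
  rri <- resample_rri(beats, rr_det)
  rri_raw <- resample_rri(beats, beats$rr)
  if (!is.null(recording$resp)) {
    resp_raw <- series_crop(recording$resp, start - 2, end + 2)
    resp <- if (population == "infant") preprocess_infant_resp(resp_raw)
    else preprocess_adult_resp(resp_raw)
  } else if (!is.null(recording$ecg)) {
    ecg <- series_crop(recording$ecg, start - 2, end + 2)
    resp <- ecg_derived_respiration(ecg)$edr
  } else stop("recording has neither a respiration channel nor an ECG")
  # align: common span, respiration interpolated onto the RRi grid
  t_lo <- max(start, rri$t0, resp$t0)
  t_hi <- min(end, max(series_times(rri)), max(series_times(resp)))
  rri <- series_crop(rri, t_lo, t_hi)
  rri_raw <- series_crop(rri_raw, t_lo, t_hi)
  tt <- series_times(rri)
  rv <- stats::approx(series_times(resp), resp$values, xout = tt, rule = 2)$y
  resp <- uniform_series(rv, fs = rri$fs, t0 = tt[1], label = resp$label)
  resp <- series_zscore(resp)
  list(rri = rri, rri_raw = rri_raw, resp = resp,
       n_corrected = beats$n_corrected)
}

#' Compute all window-level metrics
#'
#' One call per 3-minute window: Welch band powers (HF, LF/HF) of the
#' detrended RRi, the OSP relative respiratory power Px (with selected
#' model order), mean phase coherence, mean magnitude-squared coherence
#' over 0-2 Hz, and the four-row BPRSA coupling panel (max_xcorr and MI
#' per direction and anchor kind). A failing stage yields NA for its
#' metrics and leaves the others untouched.
#'
#' @param win output of [prepare_window()].
#' @param scheme a [band_scheme()].
#' @param m_range OSP candidate orders (default `1:30`).
#' @param L,T BPRSA parameters.
#' @param metrics which metric families to compute (any of `"spectral"`,
#'   `"osp"`, `"mpc"`, `"msc"`, `"bprsa"`); default all.
#' @return a data.frame of tidy rows `metric` / `value`.
#' @export
analyze_window <- function(win, scheme, m_range = 1:30, L = 55, T = 1,
                           metrics = c("spectral", "osp", "mpc", "msc",
                                       "bprsa")) {
  rows <- list()
  add <- function(metric, value)
    rows[[length(rows) + 1L]] <<- data.frame(metric = metric, value = value)
  try_na <- function(expr) tryCatch(expr, error = function(e) NA_real_)

  if ("spectral" %in% metrics) {
    bm <- try_na({
      band_metrics(welch_psd(win$rri), scheme)
    })
    if (is.list(bm)) {
      add("hf", bm$hf_power); add("lf_hf", bm$lf_hf_ratio)
    } else { add("hf", NA_real_); add("lf_hf", NA_real_) }
  }

  if ("osp" %in% metrics) {
    fit <- try_na(osp_fit(win$rri, win$resp, m_range = m_range))
    if (inherits(fit, "osp")) {
      add("px", fit$px); add("osp_order", fit$m)
    } else { add("px", NA_real_); add("osp_order", NA_real_) }
  }

  if ("mpc" %in% metrics) add("mpc", try_na({
    phx <- instantaneous_phase(win$rri, scheme$resp_band)
    phy <- instantaneous_phase(win$resp, scheme$resp_band)
    mpc(phx, phy)
  }))
  if ("msc" %in% metrics) add("msc", try_na(mean_msc(win$rri, win$resp)$mean_msc))

  panel <- if ("bprsa" %in% metrics)
    try_na(bprsa_panel(win$rri_raw, win$resp, L = L, T = T,
                       f_resp_max = scheme$resp_band[2]))
  else NA_real_
  if (is.data.frame(panel)) {
    for (i in seq_len(nrow(panel))) {
      tag <- sub("^(rri|resp)_", "", panel$anchor_kind[i])
      add(paste0("xcorr_", panel$direction[i], "_", tag), panel$max_xcorr[i])
      add(paste0("mi_", panel$direction[i], "_", tag), panel$mi[i])
    }
  }
  do.call(rbind, rows)
}

#' Average the three stimulus windows
#'
#' Collapses the music windows to one value per metric by the arithmetic
#' mean over the available slots (NA slots dropped; the slot count is kept).
#'
#' @param rows tidy rows with columns `condition`, `music_slot`, `metric`,
#'   `value`.
#' @return tidy rows with one `music` row per metric.
#' @export
average_music <- function(rows) {
  mus <- rows[rows$condition == "music", , drop = FALSE]
  rest <- rows[rows$condition != "music", , drop = FALSE]
  if (nrow(mus) == 0L) return(rest)
  agg <- stats::aggregate(value ~ metric, data = mus,
                          FUN = function(v) mean(v, na.rm = TRUE),
                          na.action = stats::na.pass)
  nsl <- stats::aggregate(value ~ metric, data = mus,
                          FUN = function(v) sum(is.finite(v)),
                          na.action = stats::na.pass)
  agg$value[nsl$value == 0] <- NA_real_
  out <- data.frame(condition = "music", music_slot = NA_integer_,
                    metric = agg$metric, value = agg$value,
                    n_slots = nsl$value)
  rest$n_slots <- 1L
  rbind(rest[, names(out)], out)
}

#' Analyze one subject across the protocol
#'
#' Runs [prepare_window()] and [analyze_window()] on every window of
#' [segment_windows()] and averages the stimulus windows.
#'
#' @param recording a `subject_recording`.
#' @param scheme a [band_scheme()]; defaults to the recording's population.
#' @param ... passed to [analyze_window()].
#' @return tidy data.frame: `condition`, `metric`, `value`, `n_slots`.
#' @export
analyze_subject <- function(recording, scheme = NULL, ...) {
  if (is.null(scheme)) scheme <- band_scheme(recording$cfg$population)
  wins <- segment_windows(recording)
  out <- lapply(seq_len(nrow(wins)), function(i) {
    res <- tryCatch({
      w <- prepare_window(recording, wins$start[i], wins$dur[i])
      analyze_window(w, scheme, ...)
    }, error = function(e) data.frame(metric = character(0),
                                      value = numeric(0)))
    if (nrow(res) == 0L) return(NULL)
    cbind(condition = wins$condition[i], music_slot = wins$music_slot[i], res)
  })
  average_music(do.call(rbind, out))
}

#' Run the full cohort pipeline
#'
#' Per-subject analysis, condition matrices per metric, Friedman omnibus
#' with Bonferroni-corrected Wilcoxon post-hocs, and the coupling
#' directionality test per condition. Fully deterministic given the
#' cohort's seeds.
#'
#' @param cohort a [generate_cohort()] result (or a list with a
#'   `recordings` list and `population` string).
#' @param gate gate post-hocs on the Friedman omnibus (default TRUE).
#' @param directionality_metric `"max_xcorr"` (default) or `"mi"`.
#' @param ... passed to [analyze_subject()].
#' @return a list of class `cohort_results`: `results` (tidy data.frame
#'   with subject/population/condition/metric/value), `stats` (per-metric
#'   omnibus + post-hocs), `directionality` (per-condition test results).
#' @export
run_cohort <- function(cohort, gate = TRUE,
                       directionality_metric = c("max_xcorr", "mi"), ...) {
  directionality_metric <- match.arg(directionality_metric)
  recs <- cohort$recordings
  res <- lapply(seq_along(recs), function(i) {
    tab <- analyze_subject(recs[[i]], ...)
    cbind(subject = i, population = cohort$population, tab)
  })
  results <- do.call(rbind, res)
  stats_out <- cohort_stats(results, gate = gate)
  dir_out <- cohort_directionality(results, metric = directionality_metric)
  structure(list(results = results, stats = stats_out,
                 directionality = dir_out, population = cohort$population),
            class = "cohort_results")
}

#' @export
print.cohort_results <- function(x, ...) {
  cat(sprintf("<cohort_results>  %d subjects (%s), %d metrics\n",
              length(unique(x$results$subject)), x$population,
              length(unique(x$results$metric))))
  for (m in names(x$stats)) {
    fr <- attr(x$stats[[m]], "friedman")
    cat(sprintf("  %-28s chi2(%d) = %6.3f, p = %.4f\n", m, fr$df, fr$chi2,
                fr$p_value))
  }
  for (cond in names(x$directionality)) {
    d <- x$directionality[[cond]]
    cat(sprintf("  directionality [%s]: V = %s, p_adj = %.4f, winner = %s\n",
                cond, format(d$V), d$p_adj, d$winner))
  }
  invisible(x)
}

#' Per-metric condition matrix from tidy results
#' @param results tidy results table from [run_cohort()].
#' @param metric metric name.
#' @return a [condition_matrix()].
#' @export
metric_matrix <- function(results, metric) {
  sub <- results[results$metric == metric, c("subject", "condition", "value")]
  wide <- stats::reshape(sub, idvar = "subject", timevar = "condition",
                         direction = "wide")
  cols <- paste0("value.", c("pre", "music", "post"))
  cols <- cols[cols %in% names(wide)]
  m <- as.matrix(wide[, cols, drop = FALSE])
  colnames(m) <- sub("^value\\.", "", cols)
  condition_matrix(m, conditions = colnames(m))
}

#' Group statistics for every scalar metric
#' @param results tidy results table.
#' @param gate gate post-hocs on the Friedman omnibus.
#' @param metrics metric names; defaults to the scalar window metrics.
#' @return named list of [posthoc_wilcoxon()] tables (with the Friedman
#'   result attached as attribute `friedman`).
#' @export
cohort_stats <- function(results, gate = TRUE, metrics = NULL) {
  if (is.null(metrics))
    metrics <- intersect(c("hf", "lf_hf", "px", "mpc", "msc"),
                         unique(results$metric))
  out <- lapply(metrics, function(m) {
    cm <- metric_matrix(results, m)
    if (nrow(cm) < 6L || ncol(cm) < 3L) return(NULL)
    posthoc_wilcoxon(cm, gate = gate)
  })
  names(out) <- metrics
  out[!vapply(out, is.null, logical(1))]
}

#' Directionality tests per condition from tidy results
#' @param results tidy results table.
#' @param metric `"max_xcorr"` or `"mi"`.
#' @param conditions protocol phases to test.
#' @return named list of [directionality_test()] results.
#' @export
cohort_directionality <- function(results, metric = "max_xcorr",
                                  conditions = c("pre", "music", "post")) {
  pref <- if (metric == "max_xcorr") "xcorr" else "mi"
  grab <- function(cond, name) {
    sub <- results[results$condition == cond & results$metric == name, ]
    sub$value[order(sub$subject)]
  }
  out <- lapply(conditions, function(cond) {
    a <- cbind(grab(cond, paste0(pref, "_rri_to_resp_accel")),
               grab(cond, paste0(pref, "_rri_to_resp_decel")))
    b <- cbind(grab(cond, paste0(pref, "_resp_to_rri_max")),
               grab(cond, paste0(pref, "_resp_to_rri_min")))
    directionality_test(a, b, n_conditions = length(conditions))
  })
  names(out) <- conditions
  out
}
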