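#' RR acceleration / deceleration anchor points
#'
#' Anchors on the (non-detrended) RRi series with averaging horizon `T`:
#' a deceleration anchor at sample `i` satisfies
#' `mean(x[i..i+T-1]) > mean(x[i-T..i-1])` (RR lengthening = heart-rate
#' deceleration); acceleration is the reverse. With the default `T = 1`
#' this reduces to `x[i] > x[i-1]` / `x[i] < x[i-1]`. Ties are excluded
#' from both sets, and anchors whose `[i - L, i + L - 1]` window would run
#' off the series are dropped.
#'
#' @param rri a `uniform_series` (raw RRi branch) or numeric vector.
#' @param mode `"accel"` or `"decel"`.
#' @param T averaging horizon in samples (default 1).
#' @param L window half-length in samples used to pre-filter anchors whose
#'   window would be infeasible; `L = 0` (default) keeps all anchors and
#'   leaves feasibility to [prsa_curve()].
#' @param min_anchors minimum anchors for a valid set (default 10).
#' @return an object of class `anchor_set`: `indices`, `kind`, `M`, `valid`.
#' @export
find_rri_anchors <- function(rri, mode = c("accel", "decel"), T = 1, L = 0,
                             min_anchors = 10) {
  mode <- match.arg(mode)
  x <- if (inherits(rri, "uniform_series")) rri$values else as.numeric(rri)
  n <- length(x)
  if (T < 1) stop("T must be >= 1")
  idx <- seq(T + 1L, n - T + 1L)
  fwd <- vapply(idx, function(i) mean(x[i:(i + T - 1L)]), numeric(1))
  bwd <- vapply(idx, function(i) mean(x[(i - T):(i - 1L)]), numeric(1))
  hit <- if (mode == "decel") fwd > bwd else fwd < bwd
  anchors <- idx[hit]
  if (L > 0) anchors <- anchors[anchors - L >= 1L & anchors + L - 1L <= n]
  kind <- if (mode == "decel") "rri_decel" else "rri_accel"
  new_anchor_set(anchors, kind, min_anchors)
}

#' Respiratory-cycle maximum / minimum anchor points
#'
#' Cycles of the z-scored respiration are delimited by upward zero
#' crossings; cycles shorter than `0.5 / f_resp_max` seconds are merged
#' away as noise crossings. Each cycle contributes one anchor: the index
#' of its maximum (or minimum).
#'
#' @param resp a z-scored `uniform_series`.
#' @param mode `"max"` or `"min"`.
#' @param f_resp_max upper edge of the population respiratory band in Hz
#'   (adult 0.5, infant 1.5).
#' @param L,min_anchors as in [find_rri_anchors()].
#' @return an `anchor_set` of kind `"resp_max"` or `"resp_min"`.
#' @export
find_resp_anchors <- function(resp, mode = c("max", "min"), f_resp_max = 0.5,
                              L = 0, min_anchors = 10) {
  mode <- match.arg(mode)
  x <- if (inherits(resp, "uniform_series")) resp$values else as.numeric(resp)
  fs <- if (inherits(resp, "uniform_series")) resp$fs else 4
  n <- length(x)
  kind <- paste0("resp_", mode)
  if (stats::sd(x) == 0) return(new_anchor_set(integer(0), kind, min_anchors))
  up <- which(x[-n] <= 0 & x[-1] > 0)
  min_len <- max(1L, round(0.5 / f_resp_max * fs))
  if (length(up) >= 2L) {
    keep <- c(TRUE, diff(up) >= min_len)
    up <- up[keep]
  }
  if (length(up) < 2L) return(new_anchor_set(integer(0), kind, min_anchors))
  pick <- if (mode == "max") which.max else which.min
  anchors <- vapply(seq_len(length(up) - 1L), function(k) {
    seg <- up[k]:(up[k + 1L] - 1L)
    seg[pick(x[seg])]
  }, integer(1))
  if (L > 0) anchors <- anchors[anchors - L >= 1L & anchors + L - 1L <= n]
  new_anchor_set(anchors, kind, min_anchors)
}

new_anchor_set <- function(indices, kind, min_anchors) {
  structure(list(indices = as.integer(indices), kind = kind,
                 M = length(indices), valid = length(indices) >= min_anchors),
            class = "anchor_set")
}

#' @export
print.anchor_set <- function(x, ...) {
  cat(sprintf("<anchor_set '%s'>  M = %d%s\n", x$kind, x$M,
              if (x$valid) "" else " (invalid: too few anchors)"))
  invisible(x)
}

#' Phase-rectified signal average over an anchor set
#'
#' Averages fixed windows of the target signal around the anchor indices:
#' `curve(k) = mean over anchors i of target[i + k]`, `k = -L .. L-1`.
#' With target equal to the trigger this is the monovariate PRSA; with a
#' different target it is the bivariate PRSA in the trigger-to-target
#' direction.
#'
#' @param target a `uniform_series` or numeric vector (same grid as the
#'   trigger the anchors came from).
#' @param anchors an `anchor_set`.
#' @param L window half-length in samples (default 55).
#' @return an object of class `prsa_curve`: `values` (length `2L`), `k`
#'   (sample offsets), `kind`, `M`.
#' @export
prsa_curve <- function(target, anchors, L = 55) {
  stopifnot(inherits(anchors, "anchor_set"))
  y <- if (inherits(target, "uniform_series")) target$values else as.numeric(target)
  idx <- anchors$indices
  idx <- idx[idx - L >= 1L & idx + L - 1L <= length(y)]
  if (length(idx) == 0L) stop("no feasible anchors for this target length")
  k <- (-L):(L - 1L)
  win <- outer(idx, k, `+`)
  vals <- colMeans(matrix(y[win], nrow = length(idx)))
  structure(list(values = vals, k = k, kind = anchors$kind, M = length(idx)),
            class = "prsa_curve")
}

#' @export
print.prsa_curve <- function(x, ...) {
  cat(sprintf("<prsa_curve '%s'>  2L = %d samples, M = %d anchors, range [%.3g, %.3g]\n",
              x$kind, length(x$values), x$M, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.prsa_curve <- function(x, ...) {
  graphics::plot(x$k, x$values, type = "l", xlab = "offset (samples)",
                 ylab = "average", main = sprintf("PRSA (%s, M = %d)", x$kind, x$M), ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Coupling strength between trigger and target PRSA curves
#'
#' Scores the association between the monovariate PRSA of the trigger and
#' the bivariate PRSA of the target computed on the same anchors:
#' * `max_xcorr` — the maximum over lags of the absolute normalized
#'   cross-correlation of the two curves (Pearson correlation of the
#'   overlapping segments at each lag, so the value lies in [0, 1] and a
#'   pure shift scores 1 at its lag); lags are limited to half the curve
#'   length so every correlation rests on at least `L` paired samples;
#' * `mi` — kernel-density mutual information (nats) between the paired
#'   curve samples, Gaussian kernels with Silverman bandwidths, floored
#'   at 0.
#'
#' @param trigger_curve,target_curve `prsa_curve`s of equal length.
#' @return a list of class `coupling_strength`: `max_xcorr`, `best_lag`,
#'   `mi`, `anchor_kind`, `M`.
#' @export
coupling_strength <- function(trigger_curve, target_curve) {
  stopifnot(inherits(trigger_curve, "prsa_curve"),
            inherits(target_curve, "prsa_curve"))
  a <- trigger_curve$values; b <- target_curve$values
  if (length(a) != length(b)) stop("curve length mismatch")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    xc <- NA_real_; lag <- NA_integer_
  } else {
    n <- length(a)
    half <- n %/% 2L
    lags <- (-half):half
    cc <- vapply(lags, function(l) {
      if (l >= 0) { av <- a[1:(n - l)]; bv <- b[(1 + l):n] }
      else { av <- a[(1 - l):n]; bv <- b[1:(n + l)] }
      if (stats::sd(av) == 0 || stats::sd(bv) == 0) 0
      else stats::cor(av, bv)
    }, numeric(1))
    best <- which.max(abs(cc))
    xc <- abs(cc[best]); lag <- lags[best]
  }
  mi <- kde_mutual_information(trigger_curve$values, target_curve$values)
  structure(list(max_xcorr = xc, best_lag = lag, mi = mi,
                 anchor_kind = trigger_curve$kind, M = trigger_curve$M),
            class = "coupling_strength")
}

#' @export
print.coupling_strength <- function(x, ...) {
  cat(sprintf("<coupling_strength '%s'>  max_xcorr = %.3f (lag %d), MI = %.3f nats, M = %d\n",
              x$anchor_kind, x$max_xcorr, x$best_lag, x$mi, x$M))
  invisible(x)
}

#' Kernel-density mutual information of paired samples
#'
#' Plug-in estimator: Gaussian product-kernel densities with Silverman
#' bandwidths (`1.06 sigma n^(-1/5)` per margin), joint and marginals
#' evaluated at the sample points; `MI = mean log(f_xy / (f_x f_y))`,
#' floored at 0 nats.
#'
#' @param x,y numeric vectors of equal length (the paired curve samples).
#' @return mutual information in nats, >= 0 (NA for degenerate input).
#' @export
kde_mutual_information <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("length mismatch")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (n < 5L || sx == 0 || sy == 0) return(NA_real_)
  hx <- 1.06 * sx * n^(-1 / 5)
  hy <- 1.06 * sy * n^(-1 / 5)
  ux <- outer(x, x, `-`) / hx
  uy <- outer(y, y, `-`) / hy
  kx <- stats::dnorm(ux); ky <- stats::dnorm(uy)
  fx <- rowMeans(kx) / hx
  fy <- rowMeans(ky) / hy
  fxy <- rowMeans(kx * ky) / (hx * hy)
  max(0, mean(log(fxy / (fx * fy))))
}

#' Four-way BPRSA coupling panel for one window
#'
#' Computes the full directional panel: RRi-to-respiration coupling with
#' acceleration and deceleration anchors, and respiration-to-RRi coupling
#' with respiratory maximum and minimum anchors. Each row scores a
#' trigger-curve / target-curve pair via [coupling_strength()]. Anchor
#' sets with too few anchors yield NA rows.
#'
#' @param rri non-detrended RRi `uniform_series`.
#' @param resp z-scored respiration `uniform_series` on the same grid.
#' @param L window half-length in samples (default 55).
#' @param T RR anchor averaging horizon (default 1).
#' @param f_resp_max upper respiratory band edge for cycle detection (Hz).
#' @return a data.frame with columns `direction`, `anchor_kind`,
#'   `max_xcorr`, `mi`, `M`.
#' @export
bprsa_panel <- function(rri, resp, L = 55, T = 1, f_resp_max = 0.5) {
  row_for <- function(trigger, target, anchors, direction) {
    if (!anchors$valid)
      return(data.frame(direction = direction, anchor_kind = anchors$kind,
                        max_xcorr = NA_real_, mi = NA_real_, M = anchors$M))
    cs <- coupling_strength(prsa_curve(trigger, anchors, L),
                            prsa_curve(target, anchors, L))
    data.frame(direction = direction, anchor_kind = anchors$kind,
               max_xcorr = cs$max_xcorr, mi = cs$mi, M = cs$M)
  }
  rows <- list(
    row_for(rri, resp, find_rri_anchors(rri, "accel", T, L), "rri_to_resp"),
    row_for(rri, resp, find_rri_anchors(rri, "decel", T, L), "rri_to_resp"),
    row_for(resp, rri, find_resp_anchors(resp, "max", f_resp_max, L), "resp_to_rri"),
    row_for(resp, rri, find_resp_anchors(resp, "min", f_resp_max, L), "resp_to_rri"))
  do.call(rbind, rows)
}
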