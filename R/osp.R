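#' Delay subspace of a respiratory signal
#'
#' Builds the matrix `V = [X0, X1, ..., Xm]` whose columns are the signal and
#' its delayed copies, `Xd = [x(d), ..., x(N-m+d)]` for `d = 0..m` (1-based:
#' column `d` holds `x[(d+1):(N-m+d)]`). All columns are contiguous slices of
#' `x` of length `N - m`.
#'
#' @param x a `uniform_series` or numeric vector (respiration).
#' @param m model order (number of delays), >= 0.
#' @return a list with `V` (matrix, `m + 1` columns), `m`, and `n_rows`.
#' @export
build_delay_subspace <- function(x, m) {
  if (inherits(x, "uniform_series")) x <- x$values
  x <- as.numeric(x)
  n <- length(x)
  if (m < 0) stop("m must be >= 0")
  if (n <= m + 10L) stop("series too short for the requested order")
  nr <- n - m
  V <- vapply(0:m, function(d) x[(d + 1L):(nr + d)], numeric(nr))
  V <- matrix(V, nrow = nr)
  list(V = V, m = as.integer(m), n_rows = nr)
}

#' Orthogonal subspace decomposition of RRi onto respiration
#'
#' Projects the RR series `y` onto the subspace spanned by the respiration
#' signal and its `0..m`-sample delays, splitting it into a
#' respiration-related component `y_x` and an orthogonal residual `y_perp`,
#' with the relative respiratory power `px = |y_x|^2 / |y|^2`. Both inputs
#' are mean-removed first. The projection `P = V (V'V)^{-1} V'` is applied
#' through a QR least-squares solve rather than the explicit inverse; a
#' rank-deficient subspace falls back to the pseudoinverse with a warning.
#'
#' Rows are aligned causally: the `y` sample at time `t` is regressed on
#' `x(t), x(t-1), ..., x(t-m)`, so `y` is truncated to its last `N - m`
#' samples.
#'
#' @param y RR series (`uniform_series` or numeric).
#' @param x respiration (`uniform_series` or numeric), same length.
#' @param m model order (delays).
#' @param center mean-remove both inputs first (default TRUE; set FALSE to
#'   apply the raw projection formula to already-centred signals).
#' @return an object of class `osp` with fields `y_x`, `y_perp`, `y_aligned`,
#'   `m`, `px`, and (when produced via [select_model_order()]) the MDL/AIC
#'   traces.
#' @export
osp_decompose <- function(y, x, m, center = TRUE) {
  if (inherits(y, "uniform_series")) y <- y$values
  if (inherits(x, "uniform_series")) x <- x$values
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (stats::sd(x) == 0) stop("respiration signal is constant")
  if (center) { x <- x - mean(x); y <- y - mean(y) }
  sub <- build_delay_subspace(x, m)
  ya <- y[(m + 1L):length(y)]
  qr_v <- qr(sub$V)
  if (qr_v$rank < ncol(sub$V)) {
    warning("rank-deficient delay subspace; using pseudoinverse")
    sv <- svd(sub$V)
    pos <- sv$d > max(sv$d) * 1e-12
    coefs <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% ya) / sv$d[pos])
    y_x <- as.numeric(sub$V %*% coefs)
  } else {
    y_x <- qr.fitted(qr_v, ya)
  }
  y_perp <- ya - y_x
  tot <- sum(ya^2)
  px <- if (tot > 0) sum(y_x^2) / tot else NA_real_
  structure(list(y_x = y_x, y_perp = y_perp, y_aligned = ya,
                 m = as.integer(m), px = px, criteria = NULL),
            class = "osp")
}

#' @export
print.osp <- function(x, ...) {
  cat(sprintf("<osp>  order m = %d, n = %d, Px = %.4f\n",
              x$m, length(x$y_aligned), x$px))
  invisible(x)
}

#' @export
residuals.osp <- function(object, ...) object$y_perp

#' @export
fitted.osp <- function(object, ...) object$y_x

#' Model-order selection for the delay subspace
#'
#' Computes the residual variance of the decomposition for each candidate
#' order and scores it with both the minimum description length,
#' `MDL(m) = N log(sigma2_m) + (m + 1) log(N)`, and Akaike's criterion,
#' `AIC(m) = N log(sigma2_m) + 2 (m + 1)`. The chosen order is the smaller
#' of the two minimisers (the most parsimonious reading of using both);
#' set `criterion = "mdl"` to use MDL alone. Ties break to the smallest
#' order.
#'
#' @param y,x as in [osp_decompose()].
#' @param m_range candidate orders, default `1:30`.
#' @param criterion `"both"` (default) or `"mdl"`.
#' @return the chosen order (integer) with the per-order criterion traces
#'   attached as attribute `"criteria"`.
#' @export
select_model_order <- function(y, x, m_range = 1:30, criterion = c("both", "mdl")) {
  criterion <- match.arg(criterion)
  if (inherits(y, "uniform_series")) y <- y$values
  if (inherits(x, "uniform_series")) x <- x$values
  n <- length(y)
  sig2 <- vapply(m_range, function(m) {
    r <- osp_decompose(y, x, m)$y_perp
    max(mean(r^2), .Machine$double.eps)
  }, numeric(1))
  mdl <- n * log(sig2) + (m_range + 1) * log(n)
  aic <- n * log(sig2) + 2 * (m_range + 1)
  m_mdl <- m_range[which.min(mdl)]
  m_aic <- m_range[which.min(aic)]
  m_hat <- if (criterion == "mdl") m_mdl else min(m_mdl, m_aic)
  attr(m_hat, "criteria") <- data.frame(m = m_range, sigma2 = sig2,
                                        mdl = mdl, aic = aic)
  m_hat
}

#' Relative respiratory power of an OSP decomposition
#'
#' The fraction of RRi power captured by the respiratory subspace,
#' `Px = (y_x' y_x) / (y' y)`, in [0, 1]; the package's index of
#' respiratory sinus arrhythmia strength.
#'
#' @param res an `osp` object.
#' @return `px` as a plain number (NA when total power is zero).
#' @export
px_statistic <- function(res) {
  stopifnot(inherits(res, "osp"))
  res$px
}

#' One-call Px with automatic order selection
#'
#' Convenience wrapper: selects the model order on the window, decomposes,
#' and returns the full `osp` object with criteria traces attached.
#'
#' @inheritParams select_model_order
#' @return an `osp` object with `criteria` filled in.
#' @export
osp_fit <- function(y, x, m_range = 1:30, criterion = c("both", "mdl")) {
  m_hat <- select_model_order(y, x, m_range, criterion)
  res <- osp_decompose(y, x, as.integer(m_hat))
  res$criteria <- attr(m_hat, "criteria")
  res
}
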