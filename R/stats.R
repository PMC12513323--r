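#' Lilliefors normality test
#'
#' Kolmogorov-Smirnov test against a normal with estimated mean and sd
#' (Lilliefors correction of the null distribution). Used to screen
#' metrics before choosing nonparametric condition comparisons.
#'
#' @param values numeric vector, n >= 5, non-constant.
#' @return a list with `statistic` (D) and `p_value`.
#' @export
lilliefors_test <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 5L) stop("need at least 5 observations")
  if (stats::sd(values) == 0) stop("constant sample: normality test undefined")
  ht <- nortest::lillie.test(values)
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Condition matrix constructor
#'
#' Subjects x conditions matrix for one metric; rows with any missing cell
#' are excluded listwise (and counted).
#'
#' @param values numeric matrix or data.frame, one column per condition.
#' @param conditions column names, default `c("pre", "music", "post")`.
#' @return a numeric matrix with attribute `n_excluded`.
#' @export
condition_matrix <- function(values, conditions = c("pre", "music", "post")) {
  m <- as.matrix(values)
  if (ncol(m) != length(conditions)) stop("wrong number of condition columns")
  colnames(m) <- conditions
  keep <- stats::complete.cases(m)
  out <- m[keep, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Friedman omnibus test across protocol phases
#'
#' Rank-based Friedman chi-square (2 df for three conditions, mid-ranks for
#' ties) on a subjects x conditions matrix.
#'
#' @param m a [condition_matrix()] (or plain matrix), >= 6 rows.
#' @return a list with `chi2`, `df`, `p_value`, `n`.
#' @export
friedman_test <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 6L) stop("need at least 6 subjects")
  if (all(apply(m, 1, function(r) length(unique(r)) == 1L)))
    return(list(chi2 = 0, df = ncol(m) - 1L, p_value = 1, n = nrow(m)))
  ht <- stats::friedman.test(m)
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, n = nrow(m))
}

#' Bonferroni-corrected pairwise Wilcoxon post-hocs
#'
#' Paired signed-rank tests for the three phase contrasts (pre-music,
#' pre-post, music-post); p values multiplied by 3 and capped at 1. By
#' default the post-hocs are gated on a significant Friedman omnibus.
#' Zero differences are dropped (Wilcoxon's rule); the exact null
#' distribution is used for n <= 25 pairs without ties, the
#' continuity-corrected normal approximation otherwise.
#'
#' @param m a subjects x 3 conditions matrix.
#' @param gate require Friedman p < `alpha` before testing (default TRUE).
#' @param alpha gate level (default 0.05).
#' @return a data.frame with columns `contrast`, `V`, `p_adj` (all NA when
#'   the gate is closed), plus attribute `friedman` with the omnibus result.
#' @export
posthoc_wilcoxon <- function(m, gate = TRUE, alpha = 0.05) {
  m <- as.matrix(m)
  fr <- friedman_test(m)
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  labs <- vapply(pairs, function(p)
    paste(colnames(m)[p], collapse = "-"), character(1))
  if (gate && fr$p_value >= alpha) {
    out <- data.frame(contrast = labs, V = NA_real_, p_adj = NA_real_)
  } else {
    res <- lapply(pairs, function(p) paired_wilcoxon(m[, p[1]], m[, p[2]]))
    out <- data.frame(contrast = labs,
                      V = vapply(res, `[[`, numeric(1), "V"),
                      p_adj = pmin(1, 3 * vapply(res, `[[`, numeric(1), "p")))
  }
  attr(out, "friedman") <- fr
  out
}

# paired signed-rank test; zeros dropped, exact for n <= 25 without ties
paired_wilcoxon <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0L) return(list(V = NA_real_, p = 1))
  exact <- length(d) <= 25L && !any(duplicated(abs(d)))
  ht <- suppressWarnings(stats::wilcox.test(d, exact = exact, correct = TRUE))
  list(V = unname(ht$statistic), p = ht$p.value)
}

#' Coupling-directionality test
#'
#' Compares the two interaction directions within one condition: each
#' subject contributes two paired slots — (acceleration vs respiratory
#' maximum) and (deceleration vs respiratory minimum) — pooling to 2n
#' pairs of coupling strengths (RRi-to-respiration vs respiration-to-RRi).
#' A paired Wilcoxon signed-rank test is applied, Bonferroni-corrected
#' over the `n_conditions` protocol phases; the winner is the direction
#' with the larger median when the corrected p falls below `alpha`.
#'
#' @param rri_to_resp matrix/data.frame, subjects x 2 (accel, decel slots).
#' @param resp_to_rri matrix/data.frame, subjects x 2 (max, min slots).
#' @param n_conditions Bonferroni family size (default 3).
#' @param alpha decision level (default 0.05).
#' @return a list with `V`, `p_adj`, `winner` (`"rri_to_resp"`,
#'   `"resp_to_rri"` or `"none"`), `n_pairs`, and the direction medians.
#' @export
directionality_test <- function(rri_to_resp, resp_to_rri, n_conditions = 3,
                                alpha = 0.05) {
  a <- as.matrix(rri_to_resp); b <- as.matrix(resp_to_rri)
  if (!all(dim(a) == dim(b)) || ncol(a) != 2L)
    stop("need subjects x 2 matrices for both directions")
  x <- c(a[, 1], a[, 2])  # pooled by (subject, anchor-slot)
  y <- c(b[, 1], b[, 2])
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  wt <- paired_wilcoxon(x, y)
  p_adj <- min(1, n_conditions * wt$p)
  med_a <- stats::median(x); med_b <- stats::median(y)
  winner <- if (is.finite(p_adj) && p_adj < alpha) {
    if (med_a > med_b) "rri_to_resp" else "resp_to_rri"
  } else "none"
  list(V = wt$V, p_adj = p_adj, winner = winner, n_pairs = length(x),
       median_rri_to_resp = med_a, median_resp_to_rri = med_b)
}
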