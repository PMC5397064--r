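# Shared nonparametric statistics: Mann-Whitney U, Hodges-Lehmann interval
# for a location difference, Spearman correlation.  Thin, opinionated
# wrappers around the stats package with the conventions used throughout:
# two-sided tests, p < 0.05 significant, p < 0.01 highly significant
# (annotations only, never gates).

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test.  In `"auto"` mode the exact null distribution is
#' used whenever `n1 * n2 <= 400` and the pooled data carry no ties;
#' otherwise a tie-corrected normal approximation (with continuity
#' correction) is used.  The reported statistic `U` counts pairs
#' `(x_i, y_j)` with `x_i > y_j` (ties counted half), so
#' `U(x, y) + U(y, x) = n1 * n2`.
#'
#' @param x,y numeric samples.
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return list with `U`, `p_value`, `n1`, `n2`, `method`, `significant`
#'   (p < 0.05) and `highly_significant` (p < 0.01).
#' @examples
#' mannWhitney(c(1, 2), c(3, 4))   # U = 0, exact p = 1/3
#' @export
mannWhitney <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(mode,
    auto = n1 * n2 <= 400 && !ties,
    exact = TRUE,
    approx = FALSE)
  if (exact && ties)
    stop("exact mode is undefined in the presence of ties")
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE))
  p <- unname(wt$p.value)
  list(U = unname(wt$statistic), p_value = p, n1 = n1, n2 = n2,
       method = if (exact) "exact" else "normal-approx",
       significant = p < 0.05, highly_significant = p < 0.01)
}

#' Hodges-Lehmann estimate and confidence interval for a location difference
#'
#' Estimates the shift of `y` relative to `x` as the median of all `n1 * n2`
#' pairwise differences `y_j - x_i`, with a confidence interval derived from
#' the order statistics of the Mann-Whitney U null distribution at the
#' stated level (90 percent by default, the convention used for reporting
#' significant band shifts and particle-size differences).
#'
#' @param x,y numeric samples (`n >= 2` each).
#' @param level confidence level in (0, 1); default 0.90.
#' @return list with `estimate`, `lo`, `hi`, `level`.
#' @examples
#' hodgesLehmannCI(c(1, 2, 3), c(2, 3, 4))$estimate   # 1
#' @export
hodgesLehmannCI <- function(x, y, level = 0.90) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("both samples need at least 2 values")
  stopifnot(level > 0, level < 1)
  exact <- length(x) * length(y) <= 400 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    wilcox.test(y, x, conf.int = TRUE, conf.level = level, exact = exact))
  list(estimate = unname(wt$estimate), lo = unname(wt$conf.int[1]),
       hi = unname(wt$conf.int[2]), level = level)
}

#' Spearman rank correlation
#'
#' Rank correlation with mid-ranks for ties; the p-value uses the
#' t-distribution approximation `t = rho * sqrt((n-2)/(1-rho^2))`.
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @return list with `rho`, `p_value`, `n`.
#' @examples
#' spearmanRho(1:5, c(1, 3, 2, 4, 5))$rho   # 0.9
#' @export
spearmanRho <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("Spearman correlation is undefined for a constant input")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = unname(ct$p.value), n = n)
}

#' Pairwise group comparisons in the supplementary-table style
#'
#' Runs [mannWhitney()] on every pair of groups and attaches the 90 percent
#' Hodges-Lehmann interval for the pairs that reach significance.
#'
#' @param values numeric vector.
#' @param groups grouping factor/vector parallel to `values`.
#' @param level confidence level for the interval.
#' @return data.frame, one row per pair: `group1`, `group2`, `n1`, `n2`,
#'   `U`, `p_value`, `estimate`, `ci_lo`, `ci_hi`.
#' @export
pairwiseGroupTests <- function(values, groups, level = 0.90) {
  groups <- factor(groups)
  lev <- levels(groups)
  rows <- list()
  for (i in seq_along(lev)) for (j in seq_along(lev)) {
    if (j <= i) next
    gx <- values[groups == lev[i]]; gy <- values[groups == lev[j]]
    mw <- mannWhitney(gx, gy, mode = if (anyDuplicated(c(gx, gy))) "approx"
                                     else "auto")
    row <- data.frame(group1 = lev[i], group2 = lev[j],
                      n1 = mw$n1, n2 = mw$n2, U = mw$U,
                      p_value = mw$p_value, estimate = NA_real_,
                      ci_lo = NA_real_, ci_hi = NA_real_)
    if (mw$significant && mw$n1 >= 2 && mw$n2 >= 2) {
      hl <- hodgesLehmannCI(gx, gy, level = level)
      row$estimate <- hl$estimate; row$ci_lo <- hl$lo; row$ci_hi <- hl$hi
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
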