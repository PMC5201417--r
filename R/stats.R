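# Nonparametric group comparisons and box-plot-style summaries.

#' Mann-Whitney U test between two groups
#'
#' Two-sided rank-sum comparison. The exact null distribution is used when
#' both groups have at most 8 observations and there are no ties; otherwise
#' the normal approximation with tie correction is used. `U` is the number
#' of (a, b) pairs in which the `a` observation wins (ties count 1/2), so
#' `U_a + U_b = n_a * n_b`.
#'
#' @param a,b numeric observation vectors, non-empty.
#' @param labels group labels, length 2.
#' @return object of class `comparison_result`: `labels`, `n`, `U`, `p`,
#'   `method`, and per-group `medians` and `quartiles`.
#' @export
mann_whitney <- function(a, b, labels = c("a", "b")) {
  if (length(a) == 0 || length(b) == 0) stop_invalid("both groups must be non-empty")
  if (any(!is.finite(c(a, b)))) stop_invalid("observations must be finite")
  has_ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) <= 8 && length(b) <= 8 && !has_ties
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = TRUE))
  U <- unname(wt$statistic)
  structure(list(labels = labels, n = c(length(a), length(b)),
                 U = U, U_other = length(a) * length(b) - U,
                 p = wt$p.value,
                 method = if (exact) "exact" else "normal approximation",
                 medians = c(median(a), median(b)),
                 quartiles = rbind(quantile(a, c(0.25, 0.75)),
                                   quantile(b, c(0.25, 0.75)))),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (%s): %s (n = %d) vs %s (n = %d)\n",
              x$method, x$labels[1], x$n[1], x$labels[2], x$n[2]))
  cat(sprintf("  U = %g, p = %.4g\n", x$U, x$p))
  cat(sprintf("  medians: %.4g vs %.4g\n", x$medians[1], x$medians[2]))
  invisible(x)
}

#' Box-plot summary statistics
#'
#' Median, quartiles, whiskers at the most extreme points within
#' `1.5 * IQR` of the box edges, and the remaining points as outliers.
#'
#' @param x numeric vector.
#' @return list: `median`, `q25`, `q75`, `whisker_lo`, `whisker_hi`,
#'   `outliers`, `n`.
#' @export
box_stats <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) stop_invalid("no finite observations")
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  in_lo <- x[x >= q[1] - 1.5 * iqr]
  in_hi <- x[x <= q[3] + 1.5 * iqr]
  list(median = q[2], q25 = q[1], q75 = q[3],
       whisker_lo = min(in_lo), whisker_hi = max(in_hi),
       outliers = x[x < q[1] - 1.5 * iqr | x > q[3] + 1.5 * iqr],
       n = length(x))
}
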