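new_test_result <- function(test, statistic, p_value, n,
                            degenerate = FALSE, method = NULL) {
  structure(
    list(test = test, statistic = unname(statistic),
         p_value = unname(p_value), n = n, degenerate = degenerate,
         method = method),
    class = "wc_test_result")
}

#' @export
print.wc_test_result <- function(x, ...) {
  cat(x$test, if (!is.null(x$method)) paste0(" (", x$method, ")"),
      ": statistic = ", format(x$statistic),
      ", p = ", format(x$p_value),
      if (x$degenerate) " [degenerate]", "\n", sep = "")
  invisible(x)
}

#' Paired comparison by Wilcoxon signed-rank test
#'
#' Two-sided by default. For small samples (at most 12 non-zero paired
#' differences) the exact null distribution is used; larger samples use the
#' normal approximation. Zero differences are discarded in the usual
#' signed-rank convention; if every difference is zero the result is
#' flagged degenerate with `p_value = NA` rather than fabricating a p.
#'
#' @param x,y Equal-length paired samples.
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @param exact_max Largest n for which the exact distribution is used.
#' @return A `wc_test_result`: `statistic` (V), `p_value`, `n` (non-zero
#'   differences), `degenerate`, `method`.
#' @export
paired_rank_test <- function(x, y, alternative = "two.sided",
                             exact_max = 12) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  d <- x - y
  n <- sum(d != 0)
  if (n == 0)
    return(new_test_result("signed-rank", NA_real_, NA_real_, 0,
                           degenerate = TRUE, method = "degenerate"))
  exact <- n <= exact_max
  ht <- suppressWarnings(
    wilcox.test(x, y, paired = TRUE, alternative = alternative,
                exact = exact, correct = !exact))
  new_test_result("signed-rank", ht$statistic, ht$p.value, n,
                  method = if (exact) "exact" else "normal approximation")
}

#' Unpaired comparison by Mann-Whitney U (rank-sum) test
#'
#' Two-sided by default; exact enumeration of rank configurations for small
#' samples (smaller group at most 8 and combined at most 16), otherwise the
#' normal approximation with tie correction.
#'
#' @param x,y Independent samples (non-empty).
#' @inheritParams paired_rank_test
#' @return A `wc_test_result`: `statistic` (U for `x`), `p_value`, `n`
#'   (`c(nx, ny)`), `method`.
#' @export
unpaired_rank_test <- function(x, y, alternative = "two.sided") {
  stopifnot(length(x) >= 1, length(y) >= 1)
  exact <- min(length(x), length(y)) <= 8 && length(x) + length(y) <= 16
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = !exact))
  new_test_result("rank-sum", ht$statistic, ht$p.value,
                  c(length(x), length(y)),
                  method = if (exact) "exact" else "normal approximation")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Statistic is the maximum gap between the two empirical CDFs: 0 for
#' identical samples, 1 for disjoint supports.
#'
#' @param x,y Samples to compare (non-empty).
#' @return A `wc_test_result`: `statistic` (D), `p_value`, `n`.
#' @export
ks_test <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ht <- suppressWarnings(ks.test(x, y))
  new_test_result("Kolmogorov-Smirnov", ht$statistic, ht$p.value,
                  c(length(x), length(y)))
}

#' Bonferroni correction for multiple comparisons
#'
#' @param pvals P values of the family of m comparisons.
#' @param alpha Family-wise error rate in (0, 1).
#' @return List: `m`, `threshold` (per-test alpha/m), `reject` (logical),
#'   `p_adjusted` (`min(1, p * m)`).
#' @export
bonferroni <- function(pvals, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1, length(pvals) >= 1)
  m <- length(pvals)
  list(m = m, threshold = alpha / m, reject = pvals < alpha / m,
       p_adjusted = p.adjust(pvals, method = "bonferroni"))
}
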