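# The comparison statistics applied to per-cell and pooled measurements:
# two-sample Kolmogorov-Smirnov on speed distributions, Wilcoxon rank-sum
# on per-cell summaries, and the pooled two-proportion z-test on inward-
# flow fractions. Thin, contract-checked wrappers over base stats where an
# implementation exists; the pooled z is computed directly (prop.test's
# default is the Yates-corrected chi-square, which is not the published
# test).

test_result <- function(statistic, p_value, n1, n2, test_name) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(statistic = statistic, p_value = p_value,
                 n1 = n1, n2 = n2, test_name = test_name),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g (n1 = %d, n2 = %d)\n",
              x$test_name, x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_a - ECDF_b|`. The p-value is exact for small tie-free
#' samples (`n1 * n2 < 10000`) and asymptotic otherwise; the plain
#' asymptotic formula is visibly conservative at the per-cell sample sizes
#' this pipeline produces.
#'
#' @param a,b Non-empty numeric samples.
#' @param alternative Passed through (default two-sided).
#' @export
ks_two_sample <- function(a, b, alternative = "two.sided") {
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  kt <- suppressWarnings(stats::ks.test(a, b, alternative = alternative))
  test_result(unname(kt$statistic), kt$p.value, length(a), length(b),
              "ks_two_sample")
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Midrank ties; exact enumeration when both samples have at most 10
#' observations and there are no ties, otherwise the normal approximation
#' with continuity correction. The statistic is the Mann-Whitney U of the
#' first sample.
#'
#' @param a,b Non-empty numeric samples.
#' @param alternative Default two-sided.
#' @export
wilcoxon_rank_sum <- function(a, b, alternative = "two.sided") {
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  exact <- length(a) <= 10L && length(b) <= 10L
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = alternative,
                                            exact = exact, correct = TRUE))
  test_result(unname(wt$statistic), wt$p.value, length(a), length(b),
              "wilcoxon_rank_sum")
}

#' Pooled two-proportion z-test
#'
#' `z = (p1 - p2) / sqrt(p (1 - p) (1/n1 + 1/n2))` with the pooled
#' proportion `p = (k1 + k2) / (n1 + n2)`; two-sided normal p-value.
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @export
two_proportion_test <- function(k1, n1, k2, n2,
                                alternative = c("two.sided", "less",
                                                "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k2 >= 0)
  if (k1 > n1 || k2 > n2) stop("successes exceed trials")
  p1 <- k1 / n1; p2 <- k2 / n2
  p <- (k1 + k2) / (n1 + n2)
  se <- sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  z <- if (se > 0) (p1 - p2) / se else 0
  pv <- switch(alternative,
               two.sided = 2 * stats::pnorm(-abs(z)),
               less = stats::pnorm(z),
               greater = stats::pnorm(z, lower.tail = FALSE))
  test_result(z, min(pv, 1), n1, n2, "two_proportion_test")
}

#' Right-continuous empirical CDF
#'
#' `F(x) = #\{x_i <= x\} / n`, evaluable at any point.
#'
#' @param sample Non-empty numeric sample.
#' @return A function of one argument.
#' @export
empirical_cdf <- function(sample) {
  if (length(sample) == 0L) stop("empty sample")
  stats::ecdf(sample)
}
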