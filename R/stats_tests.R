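.test_report <- function(name, statistic, p, alpha, extra = list()) {
  structure(c(list(test_name = name, statistic = statistic,
                   p_value = p, alpha_corrected = alpha,
                   reject = p < alpha), extra),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, p = %.4g (alpha %.4g) -> %s\n",
              x$test_name, x$statistic, x$p_value, x$alpha_corrected,
              if (x$reject) "reject" else "retain"))
  invisible(x)
}

#' Two-sample two-tailed Kolmogorov-Smirnov test
#'
#' D is the maximum vertical deviation between the two empirical CDFs.
#' The p-value is exact (full enumeration of orderings) when n*m <= 10^4
#' and there are no ties, asymptotic otherwise. Typical use compares
#' separation distributions across library subsets under a Bonferroni
#' correction (e.g. 0.05/12 when twelve pairings are examined).
#'
#' @param a,b numeric samples.
#' @param alpha corrected significance level (default 0.05/12).
#' @return a `test_report`.
#' @export
ks_two_sample <- function(a, b, alpha = 0.05 / 12) {
  if (length(a) == 0 || length(b) == 0) stop("empty sample")
  exact <- length(a) * length(b) <= 1e4 && !any(duplicated(c(a, b)))
  kt <- suppressWarnings(ks.test(a, b, exact = exact))
  .test_report("two-sample Kolmogorov-Smirnov", unname(kt$statistic),
               kt$p.value, alpha, list(exact = exact))
}

#' One-sample Kolmogorov-Smirnov test of normality
#'
#' Compares the sample against a normal distribution with the sample mean
#' and standard deviation plugged in (the naive composite form; using
#' estimated parameters makes the test conservative, the Lilliefors
#' caveat, which is recorded in the report).
#'
#' @param sample numeric vector, n >= 8.
#' @param alpha corrected significance level (default 0.05/2).
#' @return a `test_report` with `skewness` of the sample attached.
#' @export
ks_normality <- function(sample, alpha = 0.05 / 2) {
  if (length(sample) < 8) stop("need at least 8 values")
  if (sd(sample) == 0) stop("zero variance")
  kt <- suppressWarnings(
    ks.test(sample, "pnorm", mean(sample), sd(sample)))
  .test_report("one-sample Kolmogorov-Smirnov vs normal",
               unname(kt$statistic), kt$p.value, alpha,
               list(skewness = skewness(sample),
                    note = "plug-in parameters; Lilliefors caveat applies"))
}

#' Two-tailed Fisher exact test for a 2 x 2 table
#'
#' Exact two-tailed p-value by summation of hypergeometric probabilities
#' no larger than that of the observed table; the conditional
#' maximum-likelihood odds ratio is reported.
#'
#' @param table 2 x 2 matrix of non-negative integer counts with all
#'   margins positive.
#' @param alpha significance level (default 0.05).
#' @return a `test_report`.
#' @export
fisher_2x2 <- function(table, alpha = 0.05) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2 x 2 table")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all margins must be positive")
  ft <- fisher.test(table)
  .test_report("Fisher exact 2x2", unname(ft$estimate), ft$p.value, alpha)
}
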