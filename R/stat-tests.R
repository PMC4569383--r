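#' Fisher's exact test on a 2x2 molecule-count table
#'
#' Exact two-sided test of association for a 2x2 contingency table, e.g.
#' crossover vs parental molecule counts in two genetic backgrounds. The
#' two-sided p-value follows the conventional minimum-likelihood rule: the
#' sum of hypergeometric probabilities of all tables (with the observed
#' margins) whose point probability does not exceed that of the observed
#' table.
#'
#' @param a,b,c,d non-negative counts, row-wise:
#'   `matrix(c(a, c, b, d), 2, 2)` i.e. rows are groups, columns outcomes.
#' @return two-sided p-value.
#' @examples
#' fisher_exact_2x2(25, 975, 4, 996)   # crossover vs parental, two strains
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort_data("counts must be non-negative integers")
  }
  if (sum(counts) == 0) abort_data("all-zero table: test undefined")
  m <- matrix(c(a, c, b, d), nrow = 2)
  stats::fisher.test(m)$p.value
}

#' Welch's unequal-variance t-test from summary statistics
#'
#' Two-sample t-test computed directly from per-group mean, standard
#' deviation and sample size — the form needed when only printed summaries
#' (e.g. "189 +/- 18 DSBs per cell, n = 28") are available. Uses the
#' Welch-Satterthwaite degrees of freedom without rounding to an integer.
#'
#' @param mean1,sd1,n1 summary statistics of group 1 (`sd >= 0`, `n >= 2`).
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @return list with `t`, `df` and two-sided `p`.
#' @examples
#' welch_t_from_summary(202, 29, 16, 189, 18, 28)
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  for (s in c(sd1, sd2)) if (s < 0) abort_data("sd must be >= 0")
  for (n in c(n1, n2)) assert_count(n, "n", min = 2L)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  se2 <- v1 + v2
  if (se2 == 0) {
    # degenerate: both groups constant
    p <- if (mean1 == mean2) 1 else 0
    return(list(t = if (mean1 == mean2) 0 else Inf * sign(mean1 - mean2),
                df = NA_real_, p = p))
  }
  tstat <- (mean1 - mean2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df = df))
}
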