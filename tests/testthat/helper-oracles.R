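# Independent oracles, kept free of the code paths they check.

# two-sided Fisher p by full enumeration: sum hypergeometric probabilities
# of all tables with the observed margins whose point probability is <=
# that of the observed table
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  x <- max(0, k - n):min(k, m)
  probs <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# explicit least-squares oracle: per-marker LOD via lm() residual sums of
# squares, with the same covariate/dominance structure as the scan
lod_lm_oracle <- function(panel) {
  n <- nrow(panel$geno)
  pooled <- length(unique(panel$cross)) > 1
  use_dom <- any(panel$cross == "F2")
  covar <- if (pooled) factor(panel$cross) else NULL
  vapply(seq_len(ncol(panel$geno)), function(j) {
    g <- panel$geno[, j]
    het <- 1 * (g == 1)
    df0 <- data.frame(y = panel$pheno)
    if (pooled) df0$cross <- covar
    rss0 <- sum(resid(lm(y ~ ., data = df0))^2)
    df1 <- df0
    df1$g <- g
    if (use_dom) df1$het <- het
    rss1 <- sum(resid(lm(y ~ ., data = df1))^2)
    (n / 2) * log10(rss0 / rss1)
  }, numeric(1))
}
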