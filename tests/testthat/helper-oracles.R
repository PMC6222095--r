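## Exhaustive enumeration oracles for the exact tests (independent of
## the implementations under test).

ks_exact_p_brute <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  ks_stat <- function(x, y) {
    g <- sort(unique(c(x, y)))
    max(abs(ecdf(x)(g) - ecdf(y)(g)))
  }
  d_obs <- ks_stat(a, b)
  combs <- combn(length(pooled), n)
  ds <- apply(combs, 2, function(idx)
    ks_stat(pooled[idx], pooled[-idx]))
  mean(ds >= d_obs - 1e-12)
}

fisher_p_brute <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, function(a)
    dhyper(a, r1, r2, c1), numeric(1))
  p_obs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
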