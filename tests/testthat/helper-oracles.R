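# Independent oracles used across the suite. These deliberately re-derive
# each statistic by brute force / first principles, never by calling the
# implementation path they check.

# two-sided Wilcoxon rank-sum p by exhaustive enumeration of all C(n, n1)
# group assignments (handles ties through mid-ranks)
oracle_rank_sum_p <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  sums <- combn(r, n1, FUN = sum)
  p_le <- mean(sums <= w_obs + 1e-9)
  p_ge <- mean(sums >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# upper-tail hypergeometric P(X >= k) from the combinatorial mass function
oracle_phyper_upper <- function(N, K, n, k) {
  if (k <= 0) return(1)
  j <- k:min(K, n)
  j <- j[(n - j) <= (N - K)]
  if (!length(j)) return(0)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# literal draw-enumeration check of the same tail (small N only)
oracle_phyper_enum <- function(N, K, n, k) {
  draws <- combn(N, n)
  hits <- colSums(draws <= K)   # items 1..K are the "ligand-positive" pairs
  mean(hits >= k)
}

# signed KS running-sum score, written as a plain loop
oracle_ks_score <- function(x, members) {
  genes <- names(x)[order(-x, names(x))]
  nh <- sum(genes %in% members)
  g <- length(genes)
  best <- 0; run <- 0
  for (gn in genes) {
    run <- run + if (gn %in% members) 1 / nh else -1 / (g - nh)
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Spearman rho via the textbook rank formula (no ties expected in callers)
oracle_spearman <- function(a, b) {
  d <- rank(a) - rank(b)
  n <- length(a)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Benjamini-Hochberg step-up, written out literally
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
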