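# Independent oracles used to freeze expected values; these deliberately use
# brute force / enumeration, not the package's own code paths.

# Exact distribution of the bootstrap argmax for a 2-replicate gene.
# For each engaged fraction j (D..H), the bootstrap value is
# pbar_j + mean of 2 residuals drawn with replacement from the pooled
# residuals; fractions are independent. Enumerates all ordered residual
# pairs (equal probability) and computes P(argmax = j) with ties broken
# toward the lighter fraction. Fixture proportions should use exact binary
# fractions so floating-point comparisons are exact.
enum_argmax_freq <- function(m) {
  stopifnot(nrow(m) == 2, ncol(m) == 7)
  pbar <- colMeans(m)
  pool <- as.numeric(sweep(m, 2, pbar))
  pair_means <- as.numeric(outer(pool, pool, "+") / 2)
  eng <- 3:7
  vals <- lapply(eng, function(j) pbar[j] + pair_means)
  p_each <- 1 / length(pair_means)
  vapply(seq_along(eng), function(jj) {
    v <- vals[[jj]]
    total <- 0
    for (x in v) {
      p <- p_each
      for (ll in seq_along(eng)) {
        if (ll == jj) next
        w <- vals[[ll]]
        p <- p * if (ll < jj) mean(w < x) else mean(w <= x)
      }
      total <- total + p
    }
    total
  }, numeric(1))
}

# Brute-force hypergeometric enrichment p-value P(N > n_obs) by enumerating
# every size-n1 subset of a universe whose first m members carry the trait.
enum_hyper_pvalue <- function(n1, n2, m, n_obs) {
  if (n1 == 0) return(0)
  subsets <- utils::combn(n2, n1)
  n_pos <- colSums(subsets <= m)
  mean(n_pos > n_obs)
}

# Direct Monte-Carlo reference for a truncated Gaussian mean on [0, 1].
mc_truncnorm_mean <- function(n, mean, sd) {
  x <- stats::rnorm(10 * n, mean, sd)
  mean(x[x >= 0 & x <= 1][seq_len(n)])
}
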