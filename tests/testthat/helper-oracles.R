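# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths.

# Fisher two-sided p by full hypergeometric enumeration with probabilities
# computed from binomial coefficients (lchoose), independent of dhyper.
oracle_fisher_two_sided <- function(a, b, c, d) {
  n <- a + b + c + d
  k <- a + c   # exposed margin
  m <- a + b   # case margin
  lo <- max(0L, k + m - n)
  hi <- min(k, m)
  xs <- lo:hi
  logp <- lchoose(m, xs) + lchoose(n - m, k - xs) - lchoose(n, k)
  probs <- exp(logp)
  p_obs <- probs[match(a, xs)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

# Two-locus EM oracle for the classic 100-homozygote + double-heterozygote
# instance: with observed allele counts fixed, the haplotype frequencies
# have a single free parameter t = f(AB) with f(ab) = t and
# f(Ab) = f(aB) = pA - t. Brute-force grid maximisation of the multinomial
# log-likelihood, refined in two stages.
oracle_em_grid <- function(n_AABB, n_aabb, n_AaBb) {
  loglik <- function(t) {
    n_AABB * 2 * log(t) + n_aabb * 2 * log(t) +
      n_AaBb * log(2 * t^2 + 2 * (0.5 - t)^2)
  }
  grid <- seq(1e-6, 0.5, length.out = 100001)
  t1 <- grid[which.max(loglik(grid))]
  fine <- seq(max(1e-9, t1 - 1e-5), min(0.5, t1 + 1e-5),
              length.out = 200001)
  fine[which.max(loglik(fine))]
}

# Cross-product odds ratio straight from the printed counts.
oracle_cross_product_or <- function(a, b, c, d) (a * d) / (b * c)
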