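# Shared fixtures and independent oracles used across the suite.

# random valid genotype dataset (mixed sexes/chromosomes, optional missing)
random_dataset <- function(N, M, miss_rate = 0, x_frac = 0) {
  counts <- matrix(sample(0:2, N * M, replace = TRUE), N, M)
  if (miss_rate > 0) counts[runif(N * M) < miss_rate] <- NA_integer_
  chrom <- rep(1L, M)
  if (x_frac > 0) chrom[seq_len(max(1L, round(x_frac * M)))] <- 23L
  genotype_dataset(counts,
                   sex = sample(c("male", "female"), N, replace = TRUE),
                   chromosome = chrom)
}

# plain-R log-likelihood: double loop, no shared code with the C++ path
loglik_oracle <- function(x, d, Q, P) {
  P <- pmin(pmax(P, 1e-6), 1 - 1e-6)
  ll <- 0
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) {
      if (d[i, j] > 0) {
        pi <- sum(Q[i, ] * P[, j])
        ll <- ll + x[i, j] * log(pi) + (d[i, j] - x[i, j]) * log(1 - pi)
      }
    }
  }
  ll
}

# K = 2 single-individual grid search over the ancestry simplex
grid_project_oracle <- function(x, d, P, step = 1e-3) {
  q1 <- seq(0, 1, by = step)
  Pc <- pmin(pmax(P, 1e-6), 1 - 1e-6)
  ll <- vapply(q1, function(a) {
    pi <- a * Pc[1, ] + (1 - a) * Pc[2, ]
    sum(x * log(pi) + (d - x) * log(1 - pi))
  }, numeric(1))
  q1[which.max(ll)]
}

# brute-force exact Wilcoxon signed-rank p over all 2^n sign assignments
wilcoxon_brute_oracle <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  W_all <- apply(signs, 1L, function(s) sum(r[s]))
  p_ge <- mean(W_all >= W_obs)
  p_le <- mean(W_all <= W_obs)
  switch(alternative,
         two.sided = min(1, 2 * min(p_ge, p_le)),
         greater = p_ge,
         less = p_le)
}
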