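# block-relaxation sweeps, unsupervised fit, projection, alignment, CV

test_that("EM sweeps never decrease the log-likelihood on mixed-ploidy data", {
  set.seed(41)
  for (rep in 1:20) {
    N <- sample(3:12, 1); M <- sample(4:20, 1); K <- sample(1:4, 1)
    ds <- random_dataset(N, M, miss_rate = 0.2, x_frac = 0.3)
    het_x <- !is.na(ds$counts) & ds$counts == 1L & ds$sex == "male" &
      rep(ds$chromosome == 23L, each = N)
    ds$counts[het_x] <- 2L
    pm <- build_ploidy(ds, "male:23")
    Q <- matrix(rgamma(N * K, 1), N, K); Q <- Q / rowSums(Q)
    P <- matrix(runif(K * M), K, M)
    ll <- log_likelihood(pm, Q, P)
    for (it in 1:5) {
      # all-missing rows/columns occur by construction; their warning is
      # exercised in a dedicated test below
      Q <- suppressWarnings(update_Q(pm, Q, P))
      ll_q <- log_likelihood(pm, Q, P)
      expect_gte(ll_q, ll - 1e-8 * (1 + abs(ll)))
      P <- suppressWarnings(update_P(pm, Q, P))
      ll_p <- log_likelihood(pm, Q, P)
      expect_gte(ll_p, ll_q - 1e-8 * (1 + abs(ll_p)))
      ll <- ll_p
    }
    expect_equal(rowSums(Q), rep(1, N), tolerance = 1e-12)
  }
})

test_that("a vertex of the simplex consistent with the data is an EM fixed point", {
  # individual drawn purely from population 1 with that assignment exact
  P <- rbind(rep(0.99, 6), rep(0.01, 6))
  ds <- genotype_dataset(matrix(2L, 1, 6))
  pm <- build_ploidy(ds)
  Q <- matrix(c(1, 0), 1, 2)
  expect_lt(max(abs(update_Q(pm, Q, P) - Q)), 1e-12)
})

test_that("iterated Q updates reach the vertex optimum found by grid search", {
  P <- rbind(c(0.99, 0.99), c(0.01, 0.01))
  ds <- genotype_dataset(matrix(2L, 1, 2))
  pm <- build_ploidy(ds)
  Q <- matrix(0.5, 1, 2)
  for (i in 1:500) Q <- update_Q(pm, Q, P)
  q_star <- grid_project_oracle(pm$x[1, ], pm$d[1, ], P)
  expect_equal(Q[1, 1], q_star, tolerance = 2e-3)
  expect_gt(Q[1, 1], 0.995)
})

test_that("update_P solves the K = 1 and indicator-Q cases in closed form", {
  # K = 1: converged frequency is the observed allele frequency
  ds <- genotype_dataset(matrix(c(2L, 1L, 0L), 3, 1))
  pm <- build_ploidy(ds)
  P1 <- update_P(pm, matrix(1, 3, 1), matrix(0.9, 1, 1))
  expect_equal(P1[1, 1], 0.5, tolerance = 1e-9)

  # indicator Q: per-cluster frequencies decouple into within-cluster AFs
  counts <- rbind(c(2L, 2L), c(2L, 0L), c(0L, 0L), c(0L, 2L))
  ds2 <- genotype_dataset(counts)
  pm2 <- build_ploidy(ds2)
  Qi <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  P <- matrix(0.5, 2, 2)
  for (i in 1:200) P <- update_P(pm2, Qi, P)
  expect_equal(P, rbind(c(1 - 1e-6, 0.5), c(1e-6, 0.5)), tolerance = 1e-6)
})

test_that("rows with no observed genotypes are left unchanged with a warning", {
  ds <- genotype_dataset(rbind(c(1L, 1L), c(NA_integer_, NA_integer_)))
  pm <- build_ploidy(ds)
  Q <- rbind(c(0.5, 0.5), c(0.3, 0.7))
  P <- matrix(runif(4), 2, 2)
  expect_warning(Q1 <- update_Q(pm, Q, P), "no observed")
  expect_identical(Q1[2, ], Q[2, ])
})

test_that("unsupervised fits are deterministic given a seed and monotone", {
  sim <- simulate_dataset(25, 60, 2, min_separation = 0.2, seed = 44)
  f1 <- fit_unsupervised(sim$ds, 2, seed = 7)
  f2 <- fit_unsupervised(sim$ds, 2, seed = 7)
  expect_identical(f1$Q, f2$Q)
  expect_identical(f1$P, f2$P)
  expect_identical(f1$loglik_trace, f2$loglik_trace)
  expect_true(all(diff(f1$loglik_trace) >= -1e-8 * (1 + abs(f1$loglik))))
  expect_true(f1$converged)

  f3 <- fit_unsupervised(sim$ds, 2, seed = 8)
  expect_false(identical(f1$Q, f3$Q))   # different start, same optimum family
})

test_that("K = 1 degenerates to observed frequencies and unit ancestry", {
  ds <- genotype_dataset(matrix(c(2L, 1L, 0L, 1L, 2L, 0L), 3, 2))
  fit <- fit_unsupervised(ds, 1, seed = 1)
  expect_equal(fit$Q, matrix(1, 3, 1), tolerance = 1e-12)
  f_obs <- colSums(ds$counts) / (2 * nrow(ds$counts))
  expect_equal(fit$P[1, ], f_obs, tolerance = 1e-6)
  expect_error(fit_unsupervised(ds, 0, seed = 1),
               class = "admixprop_input_error")
})

test_that("small-sample fits recover the maximizer, not just any point", {
  # compare the fitted optimum against long plain EM refined from the truth
  sim <- simulate_dataset(40, 300, 2, min_separation = 0.25, seed = 45)
  fit <- fit_unsupervised(sim$ds, 2, seed = 3, tol = 1e-6)
  pm <- build_ploidy(sim$ds)
  Q <- sim$Q_true; P <- sim$P_true
  for (i in 1:3000) { Q <- update_Q(pm, Q, P); P <- update_P(pm, Q, P) }
  perm <- align_clusters(P, fit$P)
  expect_lt(max(abs(fit$Q[, perm] - Q)), 0.02)
  expect_lt(mean(abs(fit$P[perm, ] - P)), 0.01)
  expect_gte(fit$loglik, log_likelihood(pm, Q, P) - 1e-3)
})

test_that("projection matches the K = 2 grid-search oracle", {
  set.seed(46)
  for (rep in 1:10) {
    M <- 150
    P <- matrix(rbeta(2 * M, 0.5, 0.5), 2, M)
    q_true <- runif(1)
    pi <- q_true * P[1, ] + (1 - q_true) * P[2, ]
    ds <- genotype_dataset(matrix(rbinom(M, 2, pi), 1, M))
    Q <- project(ds, P)
    pm <- build_ploidy(ds)
    q_star <- grid_project_oracle(pm$x[1, ], pm$d[1, ], P)
    expect_lt(abs(Q[1, 1] - q_star), 2e-3)
  }
})

test_that("projection is per-individual: duplicates and order do not matter", {
  sim <- simulate_dataset(8, 120, 2, min_separation = 0.2, seed = 47)
  P <- sim$P_true
  Q <- project(sim$ds, P)
  # duplicated individuals give bit-identical rows
  dup <- genotype_dataset(sim$ds$counts[c(1:8, 3, 3), ],
                          sex = sim$ds$sex[c(1:8, 3, 3)])
  Qd <- project(dup, P)
  expect_identical(unname(Qd[9, ]), unname(Qd[10, ]))
  expect_identical(unname(Qd[9, ]), unname(Q[3, ]))
  # a subset projects to exactly the same rows
  sub <- genotype_dataset(sim$ds$counts[5:8, ], sex = sim$ds$sex[5:8])
  expect_identical(unname(project(sub, P)), unname(Q[5:8, ]))
})

test_that("projection rejects SNP-count mismatches", {
  sim <- simulate_dataset(4, 30, 2, seed = 48)
  expect_error(project(sim$ds, sim$P_true[, 1:29]), "mismatch",
               class = "admixprop_input_error")
})

test_that("projecting training data onto its fitted P reproduces fitted Q", {
  sim <- simulate_dataset(30, 400, 2, min_separation = 0.2, seed = 49)
  fit <- fit_unsupervised(sim$ds, 2, seed = 2)
  Q_proj <- project(sim$ds, fit$P)
  expect_lt(max(abs(Q_proj - fit$Q)), 1e-3)
})

test_that("align_clusters undoes label switching", {
  set.seed(50)
  P <- matrix(runif(3 * 40), 3, 40)
  expect_identical(align_clusters(P, P), 1:3)
  expect_identical(align_clusters(P, P[c(2, 1, 3), ]), c(2L, 1L, 3L))
  # agreement with an explicit brute-force search on noisy copies
  for (rep in 1:10) {
    perm <- sample(3)
    P2 <- P[perm, ] + matrix(rnorm(120, sd = 0.01), 3, 40)
    P2 <- pmin(pmax(P2, 0), 1)
    got <- align_clusters(P, P2)
    perms <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
    costs <- apply(perms, 1, function(p)
      sum(vapply(1:3, function(k) mean(abs(P[k, ] - P2[p[k], ])), numeric(1))))
    expect_identical(got, as.integer(perms[which.min(costs), ]))
  }
  expect_error(align_clusters(P, P[, 1:10]), class = "admixprop_input_error")
})

test_that("cross-validation is seeded, partitions entries, and ranks models", {
  sim <- simulate_dataset(20, 120, 2, min_separation = 0.2, seed = 51)
  e1 <- cross_validate(sim$ds, sim$P_true, folds = 4, seed = 5)
  e2 <- cross_validate(sim$ds, sim$P_true, folds = 4, seed = 5)
  expect_identical(e1, e2)
  expect_error(cross_validate(sim$ds, sim$P_true, folds = 1, seed = 5),
               class = "admixprop_input_error")

  # data simulated from P beats a SNP-shuffled (mismatched) P, over 10 seeds
  wins <- vapply(1:10, function(s) {
    sim_s <- simulate_dataset(15, 150, 2, min_separation = 0.3, seed = 100 + s)
    P_bad <- sim_s$P_true[, sample(ncol(sim_s$P_true))]
    cross_validate(sim_s$ds, sim_s$P_true, folds = 3, seed = s) <
      cross_validate(sim_s$ds, P_bad, folds = 3, seed = s)
  }, logical(1))
  expect_true(all(wins))
})

test_that("cross-validation error vanishes on deterministic data", {
  # near-fixated frequencies make every masked entry perfectly predictable,
  # so the mean squared prediction error collapses to numerical noise
  P <- rbind(rep(1 - 1e-6, 40), rep(1e-6, 40))
  counts <- rbind(matrix(2L, 3, 40), matrix(0L, 3, 40))
  ds <- genotype_dataset(counts)
  err <- cross_validate(ds, P, folds = 5, seed = 3)
  expect_lt(err, 1e-6)
})
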