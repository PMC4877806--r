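#' One EM sweep over the ancestry matrix Q
#'
#' Per-individual multiplicative EM update of the ancestry rows with the
#' frequency matrix held fixed; every row lands back on the simplex and the
#' log-likelihood never decreases. Rows decouple: updating one individual
#' never changes another's result. Individuals with no observed genotypes are
#' left unchanged with a warning.
#'
#' @inheritParams log_likelihood
#' @return Updated N x K ancestry matrix.
#' @export
update_Q <- function(pm, Q, P) {
  stopifnot(inherits(pm, "ploidy_map"))
  empty <- rowSums(pm$d) == 0
  if (any(empty)) {
    warning(sprintf("%d individual(s) have no observed genotypes; left unchanged",
                    sum(empty)))
  }
  cpp_update_Q(pm$x, pm$d, Q, P)
}

#' One EM sweep over the frequency matrix P
#'
#' Per-SNP EM update of the ancestral allele frequencies with Q held fixed;
#' results are clamped to `[1e-6, 1 - 1e-6]` and the log-likelihood never
#' decreases. SNPs with no observed genotypes are left unchanged with a
#' warning.
#'
#' @inheritParams log_likelihood
#' @return Updated K x M frequency matrix.
#' @export
update_P <- function(pm, Q, P) {
  stopifnot(inherits(pm, "ploidy_map"))
  empty <- colSums(pm$d) == 0
  if (any(empty)) {
    warning(sprintf("%d SNP(s) have no observed genotypes; left unchanged",
                    sum(empty)))
  }
  cpp_update_P(pm$x, pm$d, Q, P)
}

#' Unsupervised maximum-likelihood fit
#'
#' Alternating (block-relaxation) maximization of the binomial admixture
#' log-likelihood over ancestry proportions Q and ancestral allele
#' frequencies P, starting from a seeded random initialization (Q rows uniform
#' on the simplex; P from observed per-SNP frequencies plus seeded noise).
#' Each outer iteration runs one Q sweep and one P sweep; with
#' `accel = TRUE` (default) a safeguarded squared-extrapolation step is
#' attempted on top and kept only when it improves the log-likelihood, so the
#' recorded trace is non-decreasing either way. Convergence is declared when
#' the absolute log-likelihood increase of an outer iteration drops below
#' `tol`.
#'
#' @param ds a [genotype_dataset()].
#' @param K number of ancestral populations (>= 1).
#' @param spec optional haploid spec (string or [parse_haploid_spec()] value).
#' @param seed integer seed controlling the random start.
#' @param tol absolute log-likelihood convergence tolerance.
#' @param max_iter maximum number of EM sweeps.
#' @param accel use safeguarded extrapolation acceleration.
#' @return An object of class `admix_fit` with fields `Q`, `P`,
#'   `loglik_trace`, `converged`, `n_iter`, `seed` and
#'   `n_haploid_het_dropped`.
#' @export
fit_unsupervised <- function(ds, K, spec = NULL, seed = 1L, tol = 1e-4,
                             max_iter = 2000L, accel = TRUE) {
  validate_genotype_dataset(ds)
  K <- as.integer(K)
  if (is.na(K) || K < 1L) abort_input("K must be an integer >= 1")
  N <- nrow(ds$counts); M <- ncol(ds$counts)
  if (N < K) warning(sprintf("fewer individuals (%d) than clusters (%d)", N, K))
  pm <- build_ploidy(ds, spec)

  init <- with_seed(seed, {
    Q0 <- rdirichlet_rows(N, rep(1, K))
    denom <- colSums(pm$d)
    f <- ifelse(denom > 0, colSums(pm$x) / denom, 0.5)
    P0 <- matrix(rep(f, each = K), nrow = K) +
      matrix(runif(K * M, -0.1, 0.1), nrow = K)
    list(Q = Q0, P = clamp_freq(P0))
  })
  res <- cpp_fit(pm$x, pm$d, init$Q, init$P, tol, as.integer(max_iter), accel)

  # final Q polish: replace Q by the per-individual maximizer given the
  # final P, computed exactly as project() computes it, so the reported
  # (Q, P) pair is Q-block optimal and re-projection reproduces Q
  pol <- cpp_project(pm$x, pm$d, res$P, tol, as.integer(max_iter), accel)
  Q <- pol$Q
  ll <- cpp_loglik(pm$x, pm$d, Q, res$P)
  trace <- res$trace
  if (ll >= trace[length(trace)]) trace <- c(trace, ll)

  structure(list(Q = Q, P = res$P, loglik = ll,
                 loglik_trace = trace, converged = res$converged,
                 n_iter = res$n_iter, seed = seed, K = K,
                 n_haploid_het_dropped = pm$n_haploid_het_dropped),
            class = "admix_fit")
}

#' @export
print.admix_fit <- function(x, ...) {
  cat(sprintf("admix_fit: N = %d, K = %d, log-likelihood = %.4f\n",
              nrow(x$Q), x$K, x$loglik))
  cat(sprintf("  %s after %d EM sweeps (seed %d)\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iter, x$seed))
  invisible(x)
}

#' Project individuals onto fixed ancestral allele frequencies
#'
#' Maximizes the binomial admixture likelihood over each individual's
#' ancestry row with the frequency matrix held fixed (the projection mode
#' used to carry ancestry learned from a reference panel over to new or
#' related samples). Each row is optimized independently from a deterministic
#' uniform start, so the result for an individual does not depend on which
#' other individuals are present, and identical genotype rows yield identical
#' ancestry rows. SNP matching against `P_fixed` is positional; the caller is
#' responsible for supplying the same SNPs in the same order.
#'
#' @inheritParams fit_unsupervised
#' @param P_fixed K x M frequency matrix (not modified).
#' @return N x K ancestry matrix.
#' @export
project <- function(ds, P_fixed, spec = NULL, tol = 1e-4, max_iter = 2000L,
                    accel = TRUE) {
  validate_genotype_dataset(ds)
  check_frequency_matrix(P_fixed, "P_fixed")
  if (ncol(P_fixed) != ncol(ds$counts)) {
    abort_input(sprintf(
      "SNP-count mismatch: dataset has %d SNPs but P has %d columns",
      ncol(ds$counts), ncol(P_fixed)))
  }
  pm <- build_ploidy(ds, spec)
  res <- cpp_project(pm$x, pm$d, P_fixed, tol, as.integer(max_iter), accel)
  if (any(res$empty_rows == 1L)) {
    warning(sprintf(
      "%d individual(s) have no observed genotypes; uniform ancestry returned",
      sum(res$empty_rows == 1L)))
  }
  Q <- res$Q
  rownames(Q) <- ds$sample_ids
  Q
}

# exhaustive permutation generator (small K only): each first element
# prepended to every permutation of the remaining labels
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow = 0L, ncol = n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow = nrow(sub))))
  }
  out
}

#' Resolve cluster label switching between two frequency matrices
#'
#' The admixture likelihood is invariant to permuting cluster labels; this
#' finds the permutation `sigma` minimizing
#' `sum_k mean(|P_ref[k, ] - P_other[sigma(k), ]|)`, exhaustively for
#' `K <= 8` and greedily otherwise.
#'
#' @param P_ref,P_other K x M frequency matrices on the same SNPs.
#' @return Integer permutation `sigma` such that `P_other[sigma, ]` aligns
#'   with `P_ref`.
#' @export
align_clusters <- function(P_ref, P_other) {
  check_frequency_matrix(P_ref, "P_ref")
  check_frequency_matrix(P_other, "P_other")
  if (!all(dim(P_ref) == dim(P_other))) {
    abort_input("P_ref and P_other must have identical dimensions")
  }
  K <- nrow(P_ref)
  cost <- matrix(0, K, K)   # cost[k, l] = mean |P_ref[k,] - P_other[l,]|
  for (k in seq_len(K)) {
    for (l in seq_len(K)) cost[k, l] <- mean(abs(P_ref[k, ] - P_other[l, ]))
  }
  if (K <= 8L) {
    perms <- .permutations(K)
    tot <- apply(perms, 1L, function(p) sum(cost[cbind(seq_len(K), p)]))
    as.integer(perms[which.min(tot), ])
  } else {
    sigma <- integer(K)
    used <- rep(FALSE, K)
    for (k in seq_len(K)) {
      cand <- which(!used)
      sigma[k] <- cand[which.min(cost[k, cand])]
      used[sigma[k]] <- TRUE
    }
    sigma
  }
}

#' Cross-validation error of the projection step
#'
#' Masks a seeded random fold of the non-missing genotype entries (their draw
#' counts are set to 0), re-projects the dataset onto the fixed frequencies,
#' and scores each masked entry by the squared difference between its
#' effective success count and its predicted value `d_ij * pi_hat_ij`. The
#' folds partition the observed entries; the returned error is the mean over
#' masked entries, averaged across folds. A high value indicates that the
#' projected individuals are poorly described by the reference frequencies
#' (e.g. they contain a population absent from the training set).
#'
#' @inheritParams project
#' @param folds number of folds (>= 2).
#' @param seed integer seed for the fold assignment.
#' @return Mean squared masked-entry prediction error (a single real).
#' @export
cross_validate <- function(ds, P_fixed, spec = NULL, folds = 5L, seed = 1L,
                           tol = 1e-4, max_iter = 2000L) {
  validate_genotype_dataset(ds)
  check_frequency_matrix(P_fixed, "P_fixed")
  folds <- as.integer(folds)
  if (is.na(folds) || folds < 2L) abort_input("folds must be an integer >= 2")
  if (ncol(P_fixed) != ncol(ds$counts)) {
    abort_input("SNP-count mismatch between dataset and P")
  }
  pm <- build_ploidy(ds, spec)
  obs <- which(pm$d > 0)
  if (length(obs) < folds) abort_input("dataset too small to populate folds")
  assignment <- with_seed(seed, sample(rep_len(seq_len(folds), length(obs))))

  Pc <- clamp_freq(P_fixed)
  fold_err <- numeric(folds)
  for (f in seq_len(folds)) {
    mask <- obs[assignment == f]
    d_tr <- pm$d; x_tr <- pm$x
    d_tr[mask] <- 0; x_tr[mask] <- 0
    res <- cpp_project(x_tr, d_tr, P_fixed, tol, as.integer(max_iter), TRUE)
    pi_hat <- res$Q %*% Pc
    fold_err[f] <- mean((pm$x[mask] - pm$d[mask] * pi_hat[mask])^2)
  }
  mean(fold_err)
}
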