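#' Simulate an admixed genotype dataset
#'
#' Draws data with exactly the statistical structure the likelihood assumes:
#' ancestral allele frequencies independently per cluster and SNP (default
#' Beta(0.5, 0.5), a U-shaped spectrum resembling real SNP panels), ancestry
#' rows from a Dirichlet distribution, and genotypes by binomial sampling
#' from the mixed frequency `pi_ij = sum_k q_ik p_kj` -- Binomial(2, pi) at
#' diploid entries and Binomial(1, pi) at haploid entries, the latter
#' hemizygote-coded as twice the draw (so haploid genotypes are 0 or 2).
#' SNPs are independent (linkage equilibrium), matching the model and the
#' LD-thinned panels it is meant for.
#'
#' @param N,M,K numbers of individuals, SNPs and ancestral populations.
#' @param alpha Dirichlet concentration vector (length K) for ancestry rows.
#' @param beta_shape two shape parameters of the per-cluster frequency Beta
#'   distribution.
#' @param min_separation if positive, each SNP's cluster frequencies are
#'   redrawn until every pair of clusters differs by at least this much
#'   (an informative, "separated" panel).
#' @param seed integer seed; identical seeds give identical datasets.
#' @param spec optional haploid spec; individuals of the named sex are
#'   haploid at SNPs on the named chromosomes.
#' @param sex_ratio fraction of individuals that are male.
#' @param chromosome integer chromosome code per SNP (default all 1).
#' @return An object of class `sim_truth`: list with `ds`
#'   (a [genotype_dataset()]), `Q_true`, `P_true`, `seed` and `spec`.
#' @export
simulate_dataset <- function(N, M, K, alpha = rep(1, K),
                             beta_shape = c(0.5, 0.5), min_separation = 0,
                             seed = 1L, spec = NULL, sex_ratio = 0.5,
                             chromosome = rep(1L, M)) {
  if (N < 1 || M < 1 || K < 1) abort_input("N, M and K must be >= 1")
  if (length(alpha) != K || any(alpha <= 0)) {
    abort_input("alpha must be K positive reals")
  }
  if (sex_ratio < 0 || sex_ratio > 1) abort_input("sex_ratio must be in [0, 1]")
  if (length(chromosome) != M) abort_input("chromosome must have length M")
  if (!is.null(spec)) spec <- parse_haploid_spec(spec)

  with_seed(seed, {
    P <- matrix(rbeta(K * M, beta_shape[1], beta_shape[2]), nrow = K)
    if (min_separation > 0 && K >= 2) {
      for (round in seq_len(1000L)) {
        sep <- apply(P, 2L, function(p) min(dist(p)))
        bad <- which(sep < min_separation)
        if (!length(bad)) break
        P[, bad] <- rbeta(K * length(bad), beta_shape[1], beta_shape[2])
      }
    }
    Q <- rdirichlet_rows(N, alpha)
    sex <- ifelse(runif(N) < sex_ratio, "male", "female")

    pi <- Q %*% P
    d_draw <- matrix(2L, N, M)
    if (!is.null(spec)) {
      hap <- outer(sex == spec$sex, chromosome %in% spec$chromosomes, "&")
      d_draw[hap] <- 1L
    }
    counts <- matrix(rbinom(N * M, size = d_draw, prob = pi), N, M)
    if (!is.null(spec)) counts[d_draw == 1L] <- 2L * counts[d_draw == 1L]

    ds <- genotype_dataset(counts, sex = sex, chromosome = chromosome)
    structure(list(ds = ds, Q_true = Q, P_true = P, seed = seed, spec = spec),
              class = "sim_truth")
  })
}

#' Simulate sex-biased admixture on autosomes and X
#'
#' Autosomal genotypes are drawn from each individual's base ancestry; X
#' genotypes from the base ancestry shifted by a per-cluster amount `delta`
#' (rows renormalized to the simplex), haploid in males. With `delta = 0`
#' the autosomal and X expected ancestries coincide (the no-sex-bias null).
#'
#' @param N number of individuals.
#' @param M_auto,M_x numbers of autosomal and X-chromosome SNPs.
#' @param K number of ancestral populations.
#' @param Q_base base (autosomal) ancestry: a length-K simplex vector applied
#'   to every individual, or an N x K matrix.
#' @param delta length-K shift added to each row for the X chromosome; the
#'   shifted rows must remain nonnegative and are renormalized.
#' @param seed integer seed.
#' @param sex_ratio fraction of individuals that are male.
#' @param beta_shape,min_separation frequency-spectrum controls as in
#'   [simulate_dataset()].
#' @return An object of class `sim_truth` whose `ds` contains
#'   `M_auto + M_x` SNPs (chromosome 1 then chromosome 23), with extra
#'   fields `Q_x_true`, `M_auto`, `M_x`; `spec` is `male:23`.
#' @export
simulate_sex_bias <- function(N, M_auto, M_x, K, Q_base, delta = rep(0, K),
                              seed = 1L, sex_ratio = 0.5,
                              beta_shape = c(0.5, 0.5), min_separation = 0) {
  if (is.null(dim(Q_base))) {
    if (length(Q_base) != K) abort_input("Q_base vector must have length K")
    Q_base <- matrix(Q_base, nrow = N, ncol = K, byrow = TRUE)
  }
  check_ancestry_matrix(Q_base, "Q_base")
  if (length(delta) != K) abort_input("delta must have length K")
  Q_x <- sweep(Q_base, 2L, delta, "+")
  if (any(Q_x < -1e-12)) {
    abort_input("shifted X ancestry rows leave the simplex (negative entries)")
  }
  Q_x <- pmax(Q_x, 0)
  Q_x <- Q_x / rowSums(Q_x)

  spec <- parse_haploid_spec("male:23")
  with_seed(seed, {
    draw_P <- function(M) {
      P <- matrix(rbeta(K * M, beta_shape[1], beta_shape[2]), nrow = K)
      if (min_separation > 0 && K >= 2) {
        for (round in seq_len(1000L)) {
          sep <- apply(P, 2L, function(p) min(dist(p)))
          bad <- which(sep < min_separation)
          if (!length(bad)) break
          P[, bad] <- rbeta(K * length(bad), beta_shape[1], beta_shape[2])
        }
      }
      P
    }
    P_auto <- draw_P(M_auto)
    P_x <- draw_P(M_x)
    sex <- ifelse(runif(N) < sex_ratio, "male", "female")

    c_auto <- matrix(rbinom(N * M_auto, 2L, Q_base %*% P_auto), N, M_auto)
    d_x <- matrix(2L, N, M_x)
    d_x[sex == "male", ] <- 1L
    c_x <- matrix(rbinom(N * M_x, size = d_x, prob = Q_x %*% P_x), N, M_x)
    c_x[d_x == 1L] <- 2L * c_x[d_x == 1L]

    ds <- genotype_dataset(cbind(c_auto, c_x), sex = sex,
                           chromosome = c(rep(1L, M_auto), rep(23L, M_x)))
    structure(list(ds = ds, Q_true = Q_base, Q_x_true = Q_x,
                   P_true = cbind(P_auto, P_x), P_auto = P_auto, P_x = P_x,
                   M_auto = M_auto, M_x = M_x, seed = seed, spec = spec),
              class = "sim_truth")
  })
}

#' Simulate offspring of founder individuals by Mendelian transmission
#'
#' Each offspring genotype at each SNP is the sum of one allele drawn
#' uniformly from each parent's two alleles, independently across SNPs (no
#' recombination map; the model itself assumes linkage equilibrium). A
#' missing parental genotype makes the offspring genotype missing at that
#' SNP. When the founders come with ancestry truth, each offspring's expected
#' ancestry is the average of its parents'.
#'
#' @param founders a `sim_truth` from [simulate_dataset()] or a diploid
#'   [genotype_dataset()].
#' @param pairings two-column integer matrix (father index, mother index into
#'   the founders), one row per offspring.
#' @param seed integer seed.
#' @param sex_ratio fraction of offspring that are male.
#' @return List with `ds` (offspring [genotype_dataset()]), `pedigree`
#'   (data.frame: child, father, mother, sex) and, when founder truth is
#'   available, `Q_true` (mid-parent ancestry).
#' @export
simulate_pedigree <- function(founders, pairings, seed = 1L, sex_ratio = 0.5) {
  truth <- NULL
  if (inherits(founders, "sim_truth")) {
    truth <- founders
    founders_ds <- founders$ds
  } else {
    founders_ds <- founders
  }
  validate_genotype_dataset(founders_ds)
  pairings <- as.matrix(pairings)
  if (ncol(pairings) != 2L) abort_input("pairings must have two columns")
  storage.mode(pairings) <- "integer"
  Nf <- nrow(founders_ds$counts)
  if (any(is.na(pairings)) || any(pairings < 1L) || any(pairings > Nf)) {
    abort_input("pairing references an unknown founder")
  }
  n_off <- nrow(pairings)
  M <- ncol(founders_ds$counts)

  with_seed(seed, {
    transmit <- function(parent_counts) {
      # P(transmit A1) = n/2 for genotype n; NA propagates
      draws <- suppressWarnings(
        rbinom(length(parent_counts), 1L, parent_counts / 2))
      matrix(draws, nrow = n_off, ncol = M)
    }
    gf <- founders_ds$counts[pairings[, 1L], , drop = FALSE]
    gm <- founders_ds$counts[pairings[, 2L], , drop = FALSE]
    counts <- transmit(gf) + transmit(gm)
    sex <- ifelse(runif(n_off) < sex_ratio, "male", "female")

    child_ids <- sprintf("off%d", seq_len(n_off))
    ds <- genotype_dataset(counts,
                           sample_ids = child_ids, sex = sex,
                           snp_ids = founders_ds$snp_ids,
                           chromosome = founders_ds$chromosome,
                           a1 = founders_ds$a1, a2 = founders_ds$a2)
    ped <- data.frame(child = child_ids,
                      father = founders_ds$sample_ids[pairings[, 1L]],
                      mother = founders_ds$sample_ids[pairings[, 2L]],
                      sex = sex, stringsAsFactors = FALSE)
    out <- list(ds = ds, pedigree = ped)
    if (!is.null(truth)) {
      out$Q_true <- (truth$Q_true[pairings[, 1L], , drop = FALSE] +
                     truth$Q_true[pairings[, 2L], , drop = FALSE]) / 2
    }
    out
  })
}

#' Write a pedigree table to disk
#'
#' Tab-separated with columns `child`, `father`, `mother`, `sex`.
#'
#' @param pedigree the pedigree data.frame from [simulate_pedigree()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(pedigree, path) {
  utils::write.table(pedigree, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a simulated dataset and its generating truth to disk
#'
#' Emits the PLINK triplet plus `<prefix>.truth.Q` / `<prefix>.truth.P` files
#' in the standard text formats.
#'
#' @param sim a `sim_truth`.
#' @param prefix output path stem.
#' @return `prefix`, invisibly.
#' @export
write_sim_truth <- function(sim, prefix) {
  stopifnot(inherits(sim, "sim_truth"))
  write_plink(sim$ds, prefix)
  write_matrix_file(sim$Q_true, paste0(prefix, ".truth.Q"), kind = "Q")
  write_matrix_file(sim$P_true, paste0(prefix, ".truth.P"), kind = "P")
  invisible(prefix)
}
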