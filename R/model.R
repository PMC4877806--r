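#' Parse a haploid-chromosome specification string
#'
#' The specification names one sex and the chromosome codes that are haploid
#' in individuals of that sex, e.g. `"male:23,24"` for the human X and Y.
#'
#' @param arg string of the form `"<sex>:<c1>,<c2>,..."`.
#' @return An object of class `haploid_spec` with fields `sex` and
#'   `chromosomes`.
#' @export
parse_haploid_spec <- function(arg) {
  if (inherits(arg, "haploid_spec")) return(arg)
  if (!is.character(arg) || length(arg) != 1L || !nzchar(arg)) {
    abort_input("haploid spec must be a single non-empty string")
  }
  if (!grepl(":", arg, fixed = TRUE)) {
    abort_input(sprintf("malformed haploid spec '%s': expected '<sex>:<chrom,...>'", arg))
  }
  parts <- strsplit(arg, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !nzchar(parts[1])) {
    abort_input(sprintf("malformed haploid spec '%s'", arg))
  }
  chrom_str <- strsplit(parts[2], ",", fixed = TRUE)[[1]]
  if (length(chrom_str) == 0L || any(!nzchar(chrom_str))) {
    abort_input(sprintf("haploid spec '%s' has an empty chromosome list", arg))
  }
  chroms <- suppressWarnings(as.integer(chrom_str))
  if (anyNA(chroms)) {
    abort_input(sprintf("non-integer chromosome code in haploid spec '%s'", arg))
  }
  structure(list(sex = parts[1], chromosomes = unique(chroms)),
            class = "haploid_spec")
}

#' @export
print.haploid_spec <- function(x, ...) {
  cat(sprintf("haploid_spec: sex '%s', chromosomes %s\n",
              x$sex, paste(x$chromosomes, collapse = ",")))
  invisible(x)
}

#' Build the per-entry ploidy (draw-count) map of a dataset
#'
#' Unifies the diploid and haploid likelihoods through per-entry binomial draw
#' counts `d` (2 = diploid, 1 = haploid, 0 = missing/skip) and effective
#' success counts `x` (the allele count for diploid entries; half the
#' hemizygote-coded count for haploid ones). Haploid genotypes are expected to
#' be hemizygote-coded as homozygotes of the observed allele (0 or 2); a
#' heterozygous call at a haploid entry is impossible under that coding and is
#' demoted to missing with a warning tally.
#'
#' @param ds a [genotype_dataset()].
#' @param spec a `haploid_spec`, a spec string accepted by
#'   [parse_haploid_spec()], a list/vector of several such specs (each names
#'   exactly one sex), or `NULL` for all-diploid.
#' @return An object of class `ploidy_map` with fields `d` (N x M draw
#'   counts), `x` (N x M effective successes) and `n_haploid_het_dropped`.
#' @export
build_ploidy <- function(ds, spec = NULL) {
  validate_genotype_dataset(ds)
  specs <- if (is.null(spec)) list()
           else if (inherits(spec, "haploid_spec")) list(spec)
           else if (is.character(spec)) lapply(spec, parse_haploid_spec)
           else if (is.list(spec)) lapply(spec, parse_haploid_spec)
           else abort_input("invalid haploid spec")
  N <- nrow(ds$counts); M <- ncol(ds$counts)

  counts <- ds$counts
  d <- matrix(2, nrow = N, ncol = M)
  n_demoted <- 0L

  if (length(specs)) {
    if (any(ds$sex == "unknown")) {
      abort_input(paste("haploid spec names a sex but the dataset contains",
                        "individuals of unknown sex"))
    }
    hap <- matrix(FALSE, N, M)
    for (sp in specs) {
      hap <- hap | outer(ds$sex == sp$sex,
                         ds$chromosome %in% sp$chromosomes, "&")
    }
    d[hap] <- 1
    het_hap <- hap & !is.na(counts) & counts == 1L
    n_demoted <- sum(het_hap)
    if (n_demoted > 0L) {
      warning(sprintf(paste("%d heterozygous call(s) at haploid entries",
                            "demoted to missing"), n_demoted))
      counts[het_hap] <- NA_integer_
    }
  }

  miss <- is.na(counts)
  d[miss] <- 0
  x <- matrix(as.numeric(counts), nrow = N, ncol = M)
  x[miss] <- 0
  x[d == 1] <- x[d == 1] / 2

  structure(list(d = d, x = x, n_haploid_het_dropped = n_demoted,
                 N = N, M = M),
            class = "ploidy_map")
}

#' Binomial admixture log-likelihood
#'
#' Evaluates `sum over i,j of x_ij*log(pi_ij) + (d_ij - x_ij)*log(1 - pi_ij)`
#' with `pi_ij = sum_k q_ik p_kj`. With all draw counts equal to 2 this is the
#' diploid admixture log-likelihood; with draw count 1 each entry contributes
#' exactly half of the corresponding homozygous diploid term. Entries with
#' draw count 0 (missing) contribute nothing. Frequencies are clamped to
#' `[1e-6, 1 - 1e-6]` before logs are taken.
#'
#' @param pm a `ploidy_map` from [build_ploidy()].
#' @param Q N x K ancestry matrix (rows on the simplex).
#' @param P K x M frequency matrix.
#' @return The log-likelihood (a single real).
#' @export
log_likelihood <- function(pm, Q, P) {
  stopifnot(inherits(pm, "ploidy_map"))
  check_ancestry_matrix(Q)
  check_frequency_matrix(P)
  if (nrow(Q) != pm$N || ncol(P) != pm$M || ncol(Q) != nrow(P)) {
    abort_internal("shape mismatch between ploidy map, Q and P")
  }
  cpp_loglik(pm$x, pm$d, Q, P)
}
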