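#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped, absolute differences are ranked with average
#' ranks for ties, and the statistic W is the sum of the ranks of the
#' positive differences. For up to `exact_limit` nonzero pairs the p-value is
#' exact, computed by enumerating the sign-assignment distribution of the
#' rank sum (ties included, via a dynamic program over doubled ranks); beyond
#' that a normal approximation with tie correction and continuity correction
#' is used.
#'
#' @param x,y equal-length numeric vectors of paired observations; `y`
#'   defaults to zero (one-sample test on `x`).
#' @param alternative `"two.sided"` (default), `"greater"` (x tends to exceed
#'   y) or `"less"`.
#' @param exact_limit largest number of nonzero pairs for which the exact
#'   distribution is enumerated.
#' @return An object of class `htest` with `statistic` (W), `p.value`,
#'   `parameter` (`n`, the number of nonzero pairs) and `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 alternative = c("two.sided", "greater", "less"),
                                 exact_limit = 25L) {
  alternative <- match.arg(alternative)
  if (is.null(y)) y <- numeric(length(x))
  if (length(x) != length(y)) abort_input("x and y must have equal length")
  d <- x - y
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0L) {
    stop(errorCondition("all paired differences are zero",
                        class = c("admixprop_degenerate_error",
                                  "admixprop_input_error", "error", "condition")))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])

  if (n <= exact_limit) {
    # exact enumeration: distribution of 2W over all 2^n sign assignments
    r2 <- as.integer(round(2 * r))      # average ranks double to integers
    S <- sum(r2)
    f <- numeric(S + 1L)                # f[s+1] = #assignments with 2W = s
    f[1L] <- 1
    for (ri in r2) {
      f[(ri + 1L):(S + 1L)] <- f[(ri + 1L):(S + 1L)] + f[seq_len(S + 1L - ri)]
    }
    w2 <- as.integer(round(2 * W))
    total <- 2^n
    p_ge <- sum(f[(w2 + 1L):(S + 1L)]) / total
    p_le <- sum(f[seq_len(w2 + 1L)]) / total
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_ge, p_le)),
                greater = p_ge,
                less = p_le)
    method <- "Wilcoxon signed-rank test (exact)"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    sigma <- sqrt(sigma2)
    cc <- switch(alternative,
                 two.sided = sign(W - mu) * 0.5,
                 greater = 0.5,
                 less = -0.5)
    z <- (W - mu - cc) / sigma
    p <- switch(alternative,
                two.sided = min(1, 2 * pnorm(-abs(z))),
                greater = pnorm(z, lower.tail = FALSE),
                less = pnorm(z))
    method <- "Wilcoxon signed-rank test (normal approximation, tie-corrected)"
  }

  structure(list(statistic = c(W = W), p.value = p, parameter = c(n = n),
                 alternative = alternative, method = method,
                 data.name = "paired differences"),
            class = "htest")
}

#' Test for sex-biased admixture from paired ancestry estimates
#'
#' Compares each individual's X-chromosome and autosomal ancestry proportions
#' cluster by cluster: reports the mean difference `Q_x - Q_auto` and a
#' Wilcoxon signed-rank test per cluster. Under no sex bias the two sets of
#' proportions should be (nearly) equal. Ancestry estimates are assumed to be
#' on matching cluster labels (use [align_clusters()] on the two fitted
#' frequency matrices first). Raw p-values are reported; there is no
#' multiple-testing correction, and clusters are not independent tests.
#'
#' @param Q_auto,Q_x N x K ancestry matrices for the same individuals on the
#'   autosomes and the X chromosome.
#' @param one_sided if `TRUE`, test for an X excess (`Q_x > Q_auto`) instead
#'   of the two-sided default.
#' @param cluster_names optional K labels for the report.
#' @return An object of class `sex_bias_report`: data.frame with columns
#'   `component`, `mean_diff`, `W`, `p_value`, `n_nonzero`, with attributes
#'   `n_pairs` and `alternative`. Degenerate clusters (all differences zero)
#'   get `NA` statistics and are reported as non-significant.
#' @export
sex_bias_test <- function(Q_auto, Q_x, one_sided = FALSE,
                          cluster_names = NULL) {
  if (!is.matrix(Q_auto) || !is.matrix(Q_x)) {
    abort_input("Q_auto and Q_x must be matrices")
  }
  if (nrow(Q_auto) != nrow(Q_x)) {
    abort_input("Q_auto and Q_x must cover the same individuals")
  }
  if (ncol(Q_auto) != ncol(Q_x)) {
    abort_input("Q_auto and Q_x must have the same number of clusters")
  }
  K <- ncol(Q_auto)
  if (is.null(cluster_names)) cluster_names <- sprintf("cluster%d", seq_len(K))
  alternative <- if (one_sided) "greater" else "two.sided"

  rows <- lapply(seq_len(K), function(k) {
    dk <- Q_x[, k] - Q_auto[, k]
    res <- tryCatch(
      wilcoxon_signed_rank(Q_x[, k], Q_auto[, k], alternative = alternative),
      admixprop_degenerate_error = function(e) NULL)
    data.frame(component = cluster_names[k],
               mean_diff = mean(dk),
               W = if (is.null(res)) NA_real_ else unname(res$statistic),
               p_value = if (is.null(res)) NA_real_ else res$p.value,
               n_nonzero = sum(dk != 0),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  attr(report, "n_pairs") <- nrow(Q_auto)
  attr(report, "alternative") <- alternative
  class(report) <- c("sex_bias_report", "data.frame")
  report
}

#' @export
print.sex_bias_report <- function(x, ...) {
  cat(sprintf("Sex-bias report: %d paired individuals, %s test\n",
              attr(x, "n_pairs"), attr(x, "alternative")))
  cat("mean(Q_x - Q_auto) with Wilcoxon signed-rank p in parentheses:\n")
  for (i in seq_len(nrow(x))) {
    p <- x$p_value[i]
    cat(sprintf("  %-12s % .3f (%s)%s\n", x$component[i], x$mean_diff[i],
                if (is.na(p)) "degenerate" else sprintf("%.3f", p),
                if (!is.na(p) && p < 0.05) "  *" else ""))
  }
  cat("Raw p-values; no multiple-testing correction, clusters are correlated tests.\n")
  invisible(x)
}

#' Sampling-variance z-score for an allele-frequency estimate
#'
#' Under the normal approximation `f_est ~ Normal(f_ref, f_ref(1-f_ref)/2n)`
#' for a frequency estimated from `n` unrelated diploid samples, returns
#' `sqrt(2n) * (f_est - f_ref) / sqrt(f_ref * (1 - f_ref))`.
#'
#' @param f_est estimated allele frequencies (vectorized).
#' @param f_ref reference ("true") allele frequencies, strictly inside (0, 1).
#' @param n_samples number of diploid samples behind `f_est`.
#' @return z-scores, same length as `f_est`.
#' @export
af_zscore <- function(f_est, f_ref, n_samples) {
  if (any(f_ref <= 0) || any(f_ref >= 1)) {
    abort_input("f_ref must lie strictly inside (0, 1)")
  }
  if (length(n_samples) != 1L || n_samples < 1) {
    abort_input("n_samples must be a single integer >= 1")
  }
  sqrt(2 * n_samples) * (f_est - f_ref) / sqrt(f_ref * (1 - f_ref))
}

# paired one-tailed t-test p-value for mean(a) < mean(b); degenerate
# zero-variance differences collapse to the limiting 0/1 p-value
.paired_less_p <- function(a, b) {
  d <- a - b
  if (length(d) < 2L) return(NA_real_)
  s <- stats::sd(d)
  if (is.na(s) || s == 0) return(if (mean(d) < 0) 0 else 1)
  # (near-)constant differences collapse to the limiting p-value
  tryCatch(t.test(a, b, paired = TRUE, alternative = "less")$p.value,
           error = function(e) if (mean(d) < 0) 0 else 1)
}

#' Compare the accuracy of two allele-frequency estimates
#'
#' Benchmarks two estimates of the same allele frequencies against a
#' reference, after restricting to SNPs whose reference frequency lies in an
#' interior band (default 5-95 %). Reports each estimate's RMSE, a one-tailed
#' paired t-test on the per-SNP squared errors (alternative: estimate A more
#' accurate), and sampling-variance z-scores (mean, mean absolute value and
#' variance for each estimate, plus a one-tailed paired t-test on |z|).
#' Both `mean_z` and `mean_abs_z` are reported: a mean of absolute values is
#' nonnegative by construction, while the signed mean captures directional
#' bias.
#'
#' @param f_est_a,f_est_b two vectors of estimated allele frequencies.
#' @param f_ref reference frequencies of the same SNPs.
#' @param n_samples number of diploid samples behind the estimates (used for
#'   the z-scores).
#' @param band lower and upper reference-frequency bounds defining the SNPs
#'   kept (exclusive).
#' @return An object of class `af_accuracy`: list with `n_snps`, `rmse_a`,
#'   `rmse_b`, `p_sqerr_a_less_b`, `mean_z_a`, `mean_z_b`, `mean_abs_z_a`,
#'   `mean_abs_z_b`, `var_z_a`, `var_z_b`, `p_absz_a_less_b`, `z_a`, `z_b`.
#' @export
af_accuracy <- function(f_est_a, f_est_b, f_ref, n_samples,
                        band = c(0.05, 0.95)) {
  if (length(f_est_a) != length(f_ref) || length(f_est_b) != length(f_ref)) {
    abort_input("f_est_a, f_est_b and f_ref must have equal length")
  }
  keep <- f_ref > band[1] & f_ref < band[2]
  if (!any(keep)) abort_input("no SNPs left after reference-frequency filtering")
  fa <- f_est_a[keep]; fb <- f_est_b[keep]; fr <- f_ref[keep]

  err_a <- fa - fr; err_b <- fb - fr
  z_a <- af_zscore(fa, fr, n_samples)
  z_b <- af_zscore(fb, fr, n_samples)

  structure(list(
    n_snps = sum(keep),
    rmse_a = sqrt(mean(err_a^2)),
    rmse_b = sqrt(mean(err_b^2)),
    p_sqerr_a_less_b = .paired_less_p(err_a^2, err_b^2),
    mean_z_a = mean(z_a), mean_z_b = mean(z_b),
    mean_abs_z_a = mean(abs(z_a)), mean_abs_z_b = mean(abs(z_b)),
    var_z_a = stats::var(z_a), var_z_b = stats::var(z_b),
    p_absz_a_less_b = .paired_less_p(abs(z_a), abs(z_b)),
    z_a = z_a, z_b = z_b),
    class = "af_accuracy")
}

#' @export
print.af_accuracy <- function(x, ...) {
  cat(sprintf("Allele-frequency accuracy over %d SNPs:\n", x$n_snps))
  cat(sprintf("  RMSE:      A = %.4f, B = %.4f (paired one-tailed p[A<B] = %.3g)\n",
              x$rmse_a, x$rmse_b, x$p_sqerr_a_less_b))
  cat(sprintf("  mean z:    A = %+.3f, B = %+.3f\n", x$mean_z_a, x$mean_z_b))
  cat(sprintf("  mean |z|:  A = %.3f, B = %.3f (paired one-tailed p[A<B] = %.3g)\n",
              x$mean_abs_z_a, x$mean_abs_z_b, x$p_absz_a_less_b))
  cat(sprintf("  var z:     A = %.3f, B = %.3f\n", x$var_z_a, x$var_z_b))
  invisible(x)
}
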