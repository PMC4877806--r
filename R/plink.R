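#' Genotype dataset container
#'
#' Holds an N x M matrix of biallelic allele counts (number of copies of the
#' A1 allele; `NA` = missing) together with per-individual sample ids and sex
#' labels and per-SNP ids, chromosome codes and allele labels.
#'
#' @param counts integer matrix, N individuals x M SNPs, entries in
#'   `{0, 1, 2, NA}`.
#' @param sample_ids character vector of N individual ids.
#' @param sex character vector of N labels from `"male"`, `"female"`,
#'   `"unknown"`.
#' @param snp_ids character vector of M SNP ids.
#' @param chromosome integer vector of M chromosome codes (PLINK numeric
#'   convention: 23 = X, 24 = Y, 25 = XY, 26 = MT).
#' @param a1,a2 character vectors of M allele labels; `a1` is the counted
#'   allele.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(counts, sample_ids = NULL, sex = NULL,
                             snp_ids = NULL, chromosome = NULL,
                             a1 = NULL, a2 = NULL) {
  if (!is.matrix(counts)) abort_input("counts must be a matrix")
  storage.mode(counts) <- "integer"
  N <- nrow(counts)
  M <- ncol(counts)
  if (N < 1L || M < 1L) abort_input("dataset must have at least one individual and one SNP")
  if (is.null(sample_ids)) sample_ids <- sprintf("ind%d", seq_len(N))
  if (is.null(sex)) sex <- rep("unknown", N)
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%d", seq_len(M))
  if (is.null(chromosome)) chromosome <- rep(1L, M)
  if (is.null(a1)) a1 <- rep("A", M)
  if (is.null(a2)) a2 <- rep("B", M)
  ds <- structure(
    list(counts = counts,
         sample_ids = as.character(sample_ids),
         sex = as.character(sex),
         snp_ids = as.character(snp_ids),
         chromosome = as.integer(chromosome),
         a1 = as.character(a1),
         a2 = as.character(a2)),
    class = "genotype_dataset")
  validate_genotype_dataset(ds)
}

validate_genotype_dataset <- function(ds) {
  N <- nrow(ds$counts); M <- ncol(ds$counts)
  obs <- ds$counts[!is.na(ds$counts)]
  if (length(obs) && (any(obs < 0L) || any(obs > 2L))) {
    abort_input("genotype counts must be 0, 1, 2 or NA")
  }
  if (length(ds$sample_ids) != N || length(ds$sex) != N) {
    abort_input("sample_ids and sex must have one entry per individual")
  }
  if (length(ds$snp_ids) != M || length(ds$chromosome) != M ||
      length(ds$a1) != M || length(ds$a2) != M) {
    abort_input("snp_ids, chromosome, a1, a2 must have one entry per SNP")
  }
  if (!all(ds$sex %in% c("male", "female", "unknown"))) {
    abort_input("sex labels must be 'male', 'female' or 'unknown'")
  }
  invisible(ds)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d individuals x %d SNPs\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  sex: %d male, %d female, %d unknown\n",
              sum(x$sex == "male"), sum(x$sex == "female"),
              sum(x$sex == "unknown")))
  cat(sprintf("  chromosomes: %s\n",
              paste(sort(unique(x$chromosome)), collapse = ", ")))
  cat(sprintf("  missing genotypes: %.2f%%\n",
              100 * mean(is.na(x$counts))))
  invisible(x)
}

# .bed 2-bit codes (least-significant pair first within a byte):
#   00 -> 2 copies of A1, 01 -> missing, 10 -> 1 copy, 11 -> 0 copies
.bed_code_to_geno <- c(2L, NA_integer_, 1L, 0L)
.bed_geno_to_code <- function(g) {
  code <- integer(length(g))
  code[is.na(g)] <- 1L
  code[!is.na(g) & g == 2L] <- 0L
  code[!is.na(g) & g == 1L] <- 2L
  code[!is.na(g) & g == 0L] <- 3L
  code
}

# 4 x 256 table: genotype of samples 1..4 packed in each possible byte
.bed_byte_table <- local({
  b <- 0:255
  rbind(.bed_code_to_geno[bitwAnd(b, 3L) + 1L],
        .bed_code_to_geno[bitwAnd(bitwShiftR(b, 2L), 3L) + 1L],
        .bed_code_to_geno[bitwAnd(bitwShiftR(b, 4L), 3L) + 1L],
        .bed_code_to_geno[bitwAnd(bitwShiftR(b, 6L), 3L) + 1L])
})

.parse_chromosome <- function(chr) {
  chr <- as.character(chr)
  chr[chr == "X"] <- "23"; chr[chr == "Y"] <- "24"
  chr[chr == "XY"] <- "25"; chr[chr %in% c("MT", "M")] <- "26"
  out <- suppressWarnings(as.integer(chr))
  if (anyNA(out)) abort_format("unrecognized chromosome code in .bim file")
  out
}

#' Read a PLINK binary genotype fileset
#'
#' Decodes a `.bed`/`.bim`/`.fam` triplet (SNP-major `.bed` only). The counted
#' allele is A1, the first allele column of the `.bim` file, so an entry of 2
#' means homozygous A1.
#'
#' @param prefix path stem; `prefix.bed`, `prefix.bim` and `prefix.fam` must
#'   exist.
#' @return A [genotype_dataset()].
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    abort_input(paste("missing input file(s):", paste(missing, collapse = ", ")))
  }

  fam <- read.table(paths[3], header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(fam) < 5L) abort_format(".fam file must have at least 5 columns")
  sample_ids <- fam[[2]]
  sex <- c("1" = "male", "2" = "female")[fam[[5]]]
  sex[is.na(sex)] <- "unknown"

  bim <- read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(bim) < 6L) abort_format(".bim file must have 6 columns")
  chromosome <- .parse_chromosome(bim[[1]])
  snp_ids <- bim[[2]]
  a1 <- bim[[5]]; a2 <- bim[[6]]

  N <- nrow(fam); M <- nrow(bim)
  raw <- readBin(paths[1], what = "raw", n = file.size(paths[1]))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    abort_format(".bed file does not start with the PLINK magic bytes")
  }
  if (raw[3] != as.raw(0x01)) {
    abort_format("only SNP-major .bed files (mode byte 0x01) are supported")
  }
  bps <- ceiling(N / 4)                      # bytes per SNP
  if (length(raw) != 3L + bps * M) {
    abort_format(sprintf(
      ".bed length %d inconsistent with %d samples x %d SNPs (expected %d)",
      length(raw), N, M, 3L + bps * M))
  }
  body <- as.integer(raw[-(1:3)])
  geno <- .bed_byte_table[, body + 1L]       # 4 x (bps * M)
  dim(geno) <- c(4L * bps, M)
  counts <- geno[seq_len(N), , drop = FALSE]

  genotype_dataset(counts, sample_ids = sample_ids, sex = sex,
                   snp_ids = snp_ids, chromosome = chromosome,
                   a1 = a1, a2 = a2)
}

#' Write a PLINK binary genotype fileset
#'
#' Emits SNP-major `.bed` (unused high bits zero) plus matching `.bim` and
#' `.fam` files; `read_plink()` of the result reproduces counts, sex and
#' chromosome exactly.
#'
#' @param ds a [genotype_dataset()].
#' @param prefix output path stem.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(ds, prefix) {
  validate_genotype_dataset(ds)
  N <- nrow(ds$counts); M <- ncol(ds$counts)
  obs <- ds$counts[!is.na(ds$counts)]
  if (length(obs) && (any(obs < 0L) || any(obs > 2L))) {
    abort_internal("unencodable genotype entry")
  }

  bps <- ceiling(N / 4)
  code <- matrix(0L, nrow = 4L * bps, ncol = M)   # padding bits stay 00
  code[seq_len(N), ] <- .bed_geno_to_code(ds$counts)
  dim(code) <- c(4L, bps * M)
  bytes <- code[1L, ] + 4L * code[2L, ] + 16L * code[3L, ] + 64L * code[4L, ]
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, bytes)), paste0(prefix, ".bed"))

  sex_code <- c(male = "1", female = "2", unknown = "0")[ds$sex]
  fam <- paste(ds$sample_ids, ds$sample_ids, "0", "0", sex_code, "-9")
  writeLines(fam, paste0(prefix, ".fam"))

  bim <- paste(ds$chromosome, ds$snp_ids, "0", seq_len(M), ds$a1, ds$a2)
  writeLines(bim, paste0(prefix, ".bim"))
  invisible(prefix)
}

#' Read a plain-text .P or .Q matrix file
#'
#' `.P` files store ancestral allele frequencies with one row per SNP and one
#' column per cluster; the returned matrix is transposed to K x M. `.Q` files
#' store one row per individual and are returned as N x K.
#'
#' @param path file path.
#' @param kind `"P"` or `"Q"`.
#' @return Numeric matrix (K x M for `"P"`, N x K for `"Q"`).
#' @export
read_matrix_file <- function(path, kind = c("P", "Q")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort_input(paste("no such file:", path))
  nf <- count.fields(path)
  if (length(nf) == 0L) abort_format(paste("empty matrix file:", path))
  if (length(unique(nf)) != 1L) {
    abort_format(paste("ragged rows in matrix file:", path))
  }
  m <- as.matrix(read.table(path, header = FALSE))
  if (!is.numeric(m)) abort_format(paste("non-numeric entries in", path))
  if (any(m < -1e-9) || any(m > 1 + 1e-9)) {
    abort_format(paste("values outside [0, 1] in", path))
  }
  dimnames(m) <- NULL
  if (kind == "P") t(m) else m
}

#' Write a plain-text .P or .Q matrix file
#'
#' Fixed-point text with 6 decimal places, space-delimited; one SNP per row
#' for `"P"` (input K x M), one individual per row for `"Q"` (input N x K).
#'
#' @param mat numeric matrix in the in-memory orientation of its kind.
#' @param path output file path.
#' @param kind `"P"` or `"Q"`.
#' @return `path`, invisibly.
#' @export
write_matrix_file <- function(mat, path, kind = c("P", "Q")) {
  kind <- match.arg(kind)
  check_frequency_matrix(mat, what = kind)
  out <- if (kind == "P") t(mat) else mat
  lines <- apply(out, 1L, function(row) paste(sprintf("%.6f", row), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}
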