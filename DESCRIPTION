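Package: admixprop
Title: Ancestry Proportion Estimation with Projection and Haploid
    Sex-Chromosome Support
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Model-based estimation of individual ancestry proportions from
    biallelic genotypes under a binomial admixture likelihood. Provides
    unsupervised block-relaxation maximum-likelihood fitting, projection of
    new samples onto fixed ancestral allele frequencies learned from a
    reference panel, correct haploid (hemizygous) likelihoods for
    sex-chromosome genotypes, masked-genotype cross-validation diagnostics,
    Wilcoxon signed-rank tests for sex-biased admixture, allele-frequency
    accuracy diagnostics, and a synthetic-data simulator (admixed genotypes,
    sex-biased X ancestry, Mendelian pedigrees). Reads and writes PLINK
    binary genotype files (.bed/.bim/.fam) and plain-text ancestry (.Q) and
    frequency (.P) matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
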