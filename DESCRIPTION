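Package: pathperm
Title: Permutation-Based Pathway Enrichment for Case/Control GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A stratified gene-set enrichment pipeline for case/control
    genome-wide association studies. Implements standard variant and sample
    quality control (exact Hardy-Weinberg test, relatedness via method-of-moments
    pi-hat, iterative principal-component ancestry outlier removal), per-SNP
    logistic score tests with principal-component covariates, LD-aware gene-level
    statistics (sum of SNP chi-squared with a multivariate-normal empirical null),
    and permutation-based gene-set enrichment (top-percentile counting and a
    GSEA-style running sum), run across radiologic phenotype strata. Includes a
    synthetic cohort generator with LD-blocked genotypes and planted,
    stratum-specific pathway effects for end-to-end calibration and recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr,
    optparse
Config/testthat/edition: 3
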