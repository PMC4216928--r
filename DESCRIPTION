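Package: cloneCN
Title: Subclonal Copy-Number and LOH Inference from Tumor-Normal
    Whole-Genome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Joint inference of subclonal copy-number alterations (CNA) and
    loss of heterozygosity (LOH) from matched tumor/normal whole-genome
    sequencing signals. A two-chain factorial hidden Markov model over
    allele-specific genotypes and clonal clusters is fit by expectation
    maximization to per-SNP allelic counts and bias-corrected depth log
    ratios, estimating normal contamination, average tumor ploidy, and
    per-cluster cellular prevalence. Includes GC/mappability loess
    correction of binned read depth, cluster-number selection by the S_Dbw
    validity index, segment and benchmark-metric output, a synthetic
    spike-in and mixture simulator with ground truth, and a statistical
    classifier for LOH in single-nucleus sequencing data.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
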