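Package: rohcpt
Title: Population-Level Change-Point Segmentation and ROH Island Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Offline multiple change-point detection for aligned independent
    samples of a multidimensional distribution with blockwise-constant
    parameters (Bernoulli or Gaussian marginals). Provides a penalized
    maximum-likelihood estimator computed exactly by dynamic programming or
    approximated by fast hierarchical (binary) segmentation, automatic
    selection of the penalization constant by the First Repeated Value (FRV)
    grid scan, a model-based simulation harness with Jaccard-index
    evaluation, and an application layer that calls runs-of-homozygosity
    (ROH) islands from codified 0/1 SNP matrices using a physical-distance
    regularization and a quantile cutoff on block frequencies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    data.table,
    GenomicRanges,
    IRanges,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
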