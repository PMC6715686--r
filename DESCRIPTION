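Package: abcall
Title: Somatic SNV Genotyping in Single-Cell Whole-Genome Data via a
    Spatial Allele-Balance Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies somatic single-nucleotide variants in
    whole-genome-amplified single cells. Allele-specific amplification
    balance is modeled along the genome as a latent Gaussian process over
    phased heterozygous SNP read counts (binomial likelihood, blockwise
    Laplace approximation, grid-search covariance fitting) and predicted at
    candidate sites. Candidates are genotyped with an allele-balance
    consistency test and tests against pre-amplification and first-round
    amplification artifact models (Gauss-Hermite quadrature p-values with
    probability-ordered rejection regions), with artifact-test cutoffs
    tuned per candidate to a target false discovery rate using a
    multinomial bound on the true-mutation burden. Includes excess
    indel/clipping filters, multi-sample joint calling, doublet
    diagnostics, and a synthetic-data simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils,
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    tibble,
    tidyr,
    vcfR,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
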