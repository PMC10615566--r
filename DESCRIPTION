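Package: sweepscan
Title: Haplotype-Based Scans for Recent Positive Selection in Structured
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide scans for recent positive selection from phased
    SNP data in populations with fine-scale structure. Implements variant
    and sample quality control with two-stage Hardy-Weinberg recovery,
    LD pruning and PCA stratification, the integrated haplotype score
    (iHS) with derived-allele-frequency bin normalization, Hudson's F_ST
    with block-jackknife standard errors and scaled chi-square p-values,
    an identity-by-descent segment detector feeding density-of-recent-
    coalescence (DRC) statistics with an iteratively trimmed Gamma
    empirical null, and post-scan locus merging with structural-variant
    overlap filtering. A forward Wright-Fisher simulator with optional
    selective sweeps generates phased two-subpopulation panels so every
    stage is testable without cohort genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    fitdistrplus,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
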