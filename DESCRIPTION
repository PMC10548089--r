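Package: cnidomir
Title: Permutation Enrichment, miRNA Target Scanning, and qPCR
    Quantification for Cnidocyte Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the downstream analysis of miRNA knockdown
    transcriptomes in cnidarians: counts-per-million background filtering
    and dual-method differential-expression calling, permutation
    set-overlap enrichment tests with their closed-form hypergeometric
    twin, distribution of differentially expressed genes across
    single-cell cluster marker catalogues, plant-style high-complementarity
    miRNA target-site scanning with expectation-penalty scoring, and
    2^-ddCt relative quantification of stem-loop qPCR data. A synthetic
    data module generates every input the pipeline consumes with planted
    ground truth, so all stages are testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
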