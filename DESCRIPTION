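Package: microsearch
Title: Search-Based Microbiome Disease Detection and Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Phylogeny-aware microbiome sample search and search-based disease
    diagnosis. Implements a tree-structured community similarity score in which
    abundance shared at the leaves matches fully and unmatched abundance
    propagates toward the root attenuated by branch length; a two-tier search
    engine (index-key candidate prefilter plus exact rescoring) over reference
    sample databases; a rank-weighted microbiome novelty score for outlier
    detection against a healthy baseline; and a rank-weighted nearest-neighbour
    multi-cohort disease classifier. Ships the evaluation machinery used to
    characterise such a system (Cohen's kappa, ROC/AUC, rank-sum tests, host
    replicate deduplication, repeated stratified cross-validation, contamination
    simulation, baseline rarefaction) and a Dirichlet-multinomial synthetic
    cohort generator so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    biomformat,
    knitr,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
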