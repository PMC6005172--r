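Package: hgtscreen
Title: Detection and Phylogenetic Confirmation of Horizontal Gene Transfer
    in Animal Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens similarity-search results for horizontal gene transfer
    (HGT) candidates using alien-index and HGT-index scores, and confirms
    candidates with phylogenetic hypothesis tests: monophyly checks with
    contaminant pruning on unrooted gene trees, metazoan-constraint maximum
    likelihood trees fitted with an internal amino-acid likelihood engine,
    the SOWH parametric bootstrap test, and the approximately unbiased (AU)
    test via multiscale RELL resampling. Also provides developmental
    expression scoring of candidates from 3'-tag count matrices, splice-site
    and reciprocal-best-hit contamination screens, and ground-truthed
    synthetic data generators so the entire pipeline can be exercised
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
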