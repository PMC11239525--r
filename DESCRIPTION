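Package: epilineage
Title: Single-Cell Epigenomic Trajectories of Neural Organoid Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multimodal single-cell histone-modification
    (scCUT&Tag) and scRNA-seq data from branching developmental systems such as
    neural organoids. Implements cross-modality cluster matching by
    minimum-cost maximum-flow on correlation distances, terminal-fate
    absorption probabilities and pruned trajectory graphs, bivalent and
    switching chromatin-domain calling from binarized peak detection,
    pseudotemporal chromatin-state dynamics with a pseudotime-lag statistic
    for epigenetic priming, and the perturbation-arm statistics (stratified
    Cochran-Mantel-Haenszel composition tests, logistic differential
    expression, Fisher motif enrichment). A synthetic-data generator with
    planted ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    igraph,
    irlba,
    RANN,
    mgcv,
    cluster,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    clue,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
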