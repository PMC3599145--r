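Package: mpick
Title: Threshold-Free OTU Picking by Recursive Modularity Maximization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Bins 16S rRNA amplicon sequences into operational taxonomic
    units (OTUs) without a fixed distance cut-off. Pairwise global-alignment
    distances define an epsilon-neighborhood graph whose edges are weighted
    by sequence similarity; weighted-modularity maximization (a Louvain-style
    bottom-up optimizer) is applied recursively to each sub-graph until the
    maximum attainable modularity falls below a stopping threshold delta, and
    the resulting communities are reported as OTUs. Includes readers and
    writers for FASTA, sparse and square distance-matrix files, OTU membership
    tables and ground-truth label maps; an optional greedy preclustering step
    for large datasets; normalized-mutual-information validation against
    ground truth; seeded generators for Gaussian-mixture point clouds and
    multi-taxon amplicon datasets; and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
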