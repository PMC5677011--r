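Package: mpdlink
Title: Link Prediction via Matrix Perturbation and Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts missing links in weighted directed or undirected
    networks by structurally perturbing the symmetric part of the
    adjacency spectrum and then removing sparse noise with a robust-PCA
    (nuclear norm plus l1) decomposition, scoring unobserved node pairs
    from the recovered low-rank backbone. Includes the classical local
    similarity baselines (common neighbours, Adamic-Adar, resource
    allocation), precision-at-L and AUC evaluation under random
    train/probe splits, topological descriptors, and synthetic generators
    (planted low-rank plus sparse matrices, stochastic block models) so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    Matrix,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
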