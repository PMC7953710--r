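Package: glrpnet
Title: Graph Convolutional Networks with Layer-Wise Relevance Propagation
    for Molecular Networks
Version: 0.1.0
Authors@R:
    person("glrpnet", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies graph signals (for example gene expression profiles
    structured by a protein-protein interaction network) with a spectral
    graph convolutional neural network based on Chebyshev polynomial
    filters, and explains each individual prediction with Graph Layer-wise
    Relevance Propagation (GLRP), a z+ relevance rule extended to graph
    convolutional layers.  Per-sample relevance maps are turned into
    molecular subnetworks (top-k relevant vertices, singletons pruned,
    expression-tercile annotations) and scored against pathway collections
    with Fisher's exact test and a pairwise pathway-difference statistic.
    Includes seeded synthetic generators (scale-free networks, planted
    discriminative modules, image-like grid signals) used as ground truth
    in the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    digest,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
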