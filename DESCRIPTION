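Package: vesseltopo
Title: Topology-Preserving Graph Convolutional Classification of Retinal
    Arteries and Veins
Version: 0.1.0
Authors@R: person("Vessel Topology", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Classifies retinal vessel pixels into arteries and veins by
    combining a convolutional pixel classifier with a spectral graph
    convolutional network that operates on a topology-preserving pixel
    graph.  The package converts per-pixel class probabilities and feature
    maps into an undirected graph whose edges follow the segmented
    vasculature (8-connectivity) while background pixels remain isolated
    nodes, classifies the graph nodes with a two-layer graph convolutional
    network, and fuses the pixel-wise and graph-wise predictions by
    agreement voting or probability weighting.  A synthetic vascular-tree
    generator makes the full pipeline testable end to end without external
    fundus data.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
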