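Package: edgefill
Title: Two-Stage Prediction of Missing Links in Protein-Protein
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts underlying interactions between unlinked protein
    pairs in a protein-protein interaction (PPI) network and selects the
    significant part of the predictions.  Stage one scores unlinked pairs
    by the Pearson correlation of their gene expression profiles and by a
    Wang-style Gene Ontology semantic similarity, thresholding both to
    build augmented networks.  Stage two compares essential-protein
    centrality rankings (degree, subgraph and edge-clustering-coefficient
    centralities, among others) between the original and augmented
    networks, selects essential candidate proteins rescued only by the
    predicted links, and validates their incident predictions against a
    confidence-filtered reference interaction set.  Random-walk link
    prediction baselines (random walk with restart, local random walk)
    and a seeded synthetic benchmark generator are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
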