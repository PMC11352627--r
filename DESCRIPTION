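Package: synergynet
Title: Multimodal Deep Learning for Anticancer Drug Combination Synergy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the synergy score of a drug pair on a cancer cell line
    from SMILES-derived multimodal drug features and cell-line omics. Drugs are
    featurized four ways (256-bit radius-2 Morgan fingerprints, per-atom
    sequence features, molecular graphs with first/second/third-order power
    graphs, and padded 3D atomic point clouds); each modality is encoded by a
    dedicated trainable branch (BiLSTM with gated-MLP blocks fused by
    multi-head attention, a three-scale graph convolutional stack with global
    max pooling and pair-graph fusion, and a residual 1D-convolution point
    cloud embedding), cell lines are encoded from z-scored expression factors
    and binary mutation calls, and a three-layer fully connected head regresses
    the Loewe-based synergy score. Includes a purpose-built reverse-mode
    automatic differentiation engine with AdamW and step-decay learning-rate
    training, a synthetic-data generator with a documented generating function
    for end-to-end testing, cross-validation and stratified metric reporting,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: OpenBabel (>= 3.0, the obabel executable)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    ChemmineR,
    optparse,
    yaml
Config/testthat/edition: 3
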