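Package: torsioncda
Title: Torsion-Weighted Graph Learning for circRNA-Drug Association Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts circRNA-drug sensitivity associations from a bipartite
    association graph by computing the analytic torsion of the local simplicial
    complex around every association and using the log-torsion as an adaptive
    edge weight during graph-neural message propagation. Provides oriented
    clique complexes, boundary matrices, Hodge Laplacians and their
    pseudo-determinants; torsion-weighted GCN, GAT and GIN encoders with an MLP
    pair decoder trained by binary cross-entropy; Gaussian interaction profile
    kernel, k-mer and fingerprint similarity features; stratified k-fold
    cross-validation with AUC/AUPR/F1 metrics; a planted block-model simulator;
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    Biostrings,
    ChemmineR,
    ChemmineOB,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
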