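Package: liquidperc
Title: Slow-Fusion Network Models of Visual Viscosity Perception
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Desk-scale modelling pipeline for studying visual perception of
    liquid viscosity with slow-fusion video regression networks. Provides a
    procedural generator for short liquid movie clips organised in a factorial
    design (scene class by log-spaced viscosity), a synthetic rating-observer
    model, a from-scratch slow-fusion convolutional network with training,
    activation capture, artificial lesioning and frozen-prefix head retraining,
    a registry of eighteen stimulus predictors (optical flow, spectra, colour
    channels, GIST, motion energy, texture statistics, and high-level labels),
    representational similarity analysis under Euclidean and correlation
    distance conventions, k-nearest-neighbour Louvain clustering of unit tuning
    profiles, activation maximization, capacity-compression and scene-transfer
    experiments, and linear centered kernel alignment for comparing trained
    network populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    Matrix,
    igraph,
    cluster,
    pROC,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
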