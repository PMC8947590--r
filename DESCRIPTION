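Package: cdvis
Title: Corollary-Discharge Signals and Shift-Invariant Classification in
    Convolutional Network Models of the Visual System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying how corollary-discharge
    (eye-movement) signals multiplexed with visual inputs enable shift-invariant
    classification in convolutional neural networks. Generates retinotopic
    bar-localization stimuli with discretized fixational eye movements, framed
    natural-image surrogates with saccadic shifts and congruent or incongruent
    movement images, and grating and focal-spot probes. Implements the full
    network stack (convolution, max-pooling, batch normalization, movement-signal
    injection as feature images or global scalars) with mini-batch training and
    early stopping, plus the representational analyses: embedding-based decoding
    readouts (PCA and exact t-SNE with SVM/LDA), activity-mode angular separation,
    movement-signal gating profiles, saccade-direction decoding with its
    ideal-observer bounds, single-channel saccadic modulation (suppression,
    enhancement, gain fields), activation-maximization receptive fields, and
    orientation hyperacuity dissociation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    e1071,
    MASS,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
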