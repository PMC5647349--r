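Package: colonyscope
Title: Label-Free iPSC Colony Detection, Tracking and Picking-Time Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A bright-field, label-free pipeline for monitoring induced
    pluripotent stem cell (iPSC) reprogramming cultures: sliding-window
    texture classification of 96x96 patches into colony/non-colony, binary-map
    post-processing (hole filling, Gaussian re-binarization, sparse-residual
    removal), seeded random-walker colony segmentation, backward time-lapse
    tracking, growth-curve extraction, and a partially-labelled four-state
    left-to-right Gaussian hidden Markov model over growth features whose
    mature-phase posterior triggers the colony picking decision. Includes a
    synthetic bright-field scene generator with ground-truth masks, logistic
    growth trajectories, a fluorescence reporter channel and expert picking-day
    labels, so the whole pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    Matrix,
    EBImage,
    nnet,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
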