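Package: withdrawr
Title: Automated Phenotyping of Rodent Opioid-Withdrawal Behavior from
    Multi-View Video and Audio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for automated, objective scoring of spontaneous opioid
    withdrawal in rats recorded by a five-camera (one top, four side) cage rig
    with dual microphones. Reduces top-view video to a one-dimensional
    frame-difference motion signal, extracts motion segments and discards
    stationary footage, fits an ellipse to the animal silhouette to pick the
    best side camera, detects wet-dog shakes and scratching as rhythmic peak
    trains, classifies side-view clips with attention-augmented convolutional
    features (CBAM, CSPM) and key-frame majority voting, detects
    teeth-chattering click trains in audio with a mel-spectrogram
    squeeze-and-excitation network stage, and converts the detected events
    into duration-thresholded composite withdrawal scores with group
    statistics. Ships a synthetic session generator with exact ground truth
    so every stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    signal,
    nnet,
    stats,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    png,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
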