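Package: vibrotrace
Title: Sonified EEG, Vibration-Driven Laser Projection, and Pattern
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning group-averaged multichannel EEG into sound by
    direct amplitude mapping, driving a simulated speaker-membrane-mirror-laser
    apparatus with that sound, rendering the projected laser spot into frame
    sequences, isolating the projected pattern by adaptive thresholding,
    morphological opening and contour-envelope masking, extracting per-frame
    spatial descriptors (active area, Shannon entropy, box-counting fractal
    dimension, centroid trajectory), and classifying the resulting feature
    tables with a random forest under a holdout plus stratified k-fold
    cross-validation protocol with Gaussian noise-injection robustness checks.
    Includes a seedable synthetic EEG generator emulating slow-band-dominated
    and alpha-dominated group spectral profiles, membrane physics (surface
    density, fundamental-mode tension/resonance relations for a circular
    membrane), and an end-to-end reproducible pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    randomForest,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
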