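Package: zolpiscope
Title: Resting-State EEG Pipeline for Pharmacological Studies in Disorders of
    Consciousness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested resting-state EEG analysis pipeline for paired
    pharmacological studies in disorders of consciousness. Implements
    hamming-windowed FIR preprocessing with spherical-spline channel
    interpolation, Welch spectra with relative band power and brain symmetry
    indices (pdBSI, rBSI), surface-Laplacian phase-locking-value connectivity,
    polarity-invariant microstate segmentation with two-level modified k-means
    and eight feature families (including mean interval and the spatial
    correlation metric), network-based-statistic permutation inference,
    sign-flip and label-shuffle permutation tests with add-one correction, and
    leakage-safe nested leave-one-out cross-validated linear SVM/SVR models.
    A synthetic-EEG generator with known ground truth (band power recipes,
    planted phase coupling, microstate switching, paired study designs) backs
    parameter-recovery and calibration tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    readr,
    signal,
    e1071,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
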