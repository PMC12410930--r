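Package: glycopore
Title: Nanopore O-Glycopeptide Event Analysis and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for single-molecule nanopore analysis of mucin-type
    O-glycopeptides: simulation of ionic-current recordings with
    class-specific blockade depths and Eyring-type temperature-dependent
    dwell times, open-pore baseline estimation and threshold-based blockade
    event detection, per-event feature extraction (blockade ratio, duration,
    intra-event standard deviation, skewness), Gaussian population fits of
    blockade-ratio and log-duration histograms, density-based event
    denoising (HDBSCAN) and sub-population splitting, a multi-model
    supervised classification bench, capture-frequency-corrected relative
    quantification of peptide mixtures, and Eyring transition-state analysis
    of event-exit kinetics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    e1071,
    kernlab,
    randomForest,
    caret,
    rpart,
    nnet,
    pROC,
    cluster,
    mclust
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
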