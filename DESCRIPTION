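Package: movemux
Title: Movement, Glucose and Phase Multiplexing in Fiber Photometry Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for simultaneous behavioral-video and fiber
    photometry recordings. Computes a video-derived body-movement metric
    (frame differencing convolved with an indicator-decay kernel),
    preprocesses two-channel photometry (first-minute trim,
    triple-exponential bleaching correction, z-scoring), decomposes traces
    by empirical mode decomposition with normalized-Hilbert instantaneous
    attributes, and quantifies how movement and blood-glucose information
    occupy distinct frequency bands of one population signal: weighted
    circular phase-preference statistics, per-IMF multivariate regression
    with frequency binning, mixed-model comparison of behavioral versus
    movement predictors, cross-correlation lag analysis, PLS drop-one
    feature contributions, movement-bout detection with k-means size
    clustering, and pupillometry circle fitting. Includes a synthetic
    session generator with controllable ground-truth coupling so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    lme4,
    minpack.lm,
    mixOmics,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
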