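Package: gsrdistract
Title: Phasic Skin Conductance Decomposition and Driver Distraction
    Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis pipeline for identifying driver distraction
    from single-channel galvanic skin response (GSR) recordings. Decomposes
    skin conductance into tonic and phasic sudomotor drivers by regularized
    deconvolution against a biexponential (Bateman) impulse response
    (continuous decomposition analysis), segments the phasic component into
    overlapping short windows, extracts 18 spectro-temporal features
    (moments, derivative-based peak counts, short-time Fourier band powers,
    Higuchi and Katz fractal dimensions, Burg autoregressive coefficients),
    ranks features by linear SVM recursive feature elimination with a
    cross-subject consensus rule, and evaluates kernel-SVM classifiers under
    stratified 10-fold cross-validation. Includes a synthetic
    electrodermal-activity generator with known ground truth so the whole
    pipeline is testable without access to private driving data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
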