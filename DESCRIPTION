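Package: mwibelt
Title: Synthetic Microwave-Belt Imaging and Machine Learning for Lung Tumor Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end synthetic test bed for an eight-antenna wearable
    microwave belt that screens for lung tumors. Provides a Born-approximation
    forward scattering model for parametric torso phantoms, Touchstone 8-port
    S-parameter input/output, two-step clutter/skin calibration, multistatic
    frequency-domain backprojection imaging, band-averaged spectral features,
    ADASYN oversampling, gradient-boosted and convolutional detectors and tumor
    size regressors with noise-robust fine-tuning, multi-position decision
    fusion, and size-based NSCLC stage assignment.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    Rcpp,
    signal,
    stats,
    tools,
    utils,
    xgboost,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
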