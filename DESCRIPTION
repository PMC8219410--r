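Package: attneeg
Title: Attention Monitoring from EEG via Wavelet Band Power and an Improved Random Forest
Version: 0.1.0
Authors@R: person("attneeg", "developers", role = c("aut", "cre"), email = "dev@example.org")
Description: Pipeline for five-level attention monitoring from four-channel EEG:
    discrete wavelet multiresolution decomposition (Daubechies filters) with
    SURE adaptive soft-threshold denoising, per-band signal reconstruction and
    band-power feature extraction (4 channels x 5 bands), a bootstrap decision
    tree ensemble with majority voting tuned by a coarse-to-fine grid search
    under S-fold cross-validation, a five-level attention quantizer, and three
    headless closed-loop neurofeedback game controllers (sustained, selective,
    focus). Includes a synthetic EEG generator so the whole pipeline is
    testable without recorded data, evaluation metrics, a classifier
    comparison harness, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
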