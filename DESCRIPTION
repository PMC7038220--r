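Package: bispeeg
Title: Bispectrum Texture Analysis and Classification of EEG Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: An end-to-end pipeline for two-class discrimination of
    multichannel EEG recordings via higher-order spectra. Segmented,
    band-pass-filtered EEG channels are mapped to bispectrum magnitude
    images; gray-level run-length and entropy texture features are
    extracted from the images, reduced with locality sensitive
    discriminant analysis (LSDA), screened with Welch two-sample t-tests,
    and classified with a probabilistic neural network or standard
    classifiers under stratified k-fold cross-validation. Includes a
    synthetic cohort generator with controllable quadratic phase coupling
    contrast for validation, plus CSV/EDF input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    e1071,
    class,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
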