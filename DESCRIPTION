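Package: nerveloc
Title: Probe-to-Nerve Distance Prediction from Electrical Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for electrical-stimulation nerve localization in
    intraoperative neuromonitoring. Estimates the tissue equivalent circuit
    (series resistance, parallel resistance and capacitance) and impedance
    magnitude from the driven voltage waveform of a constant-current pulse,
    extracts compound muscle action potential (CMAP) features from
    trigger-aligned EMG across graded stimulus intensities, and fits a
    nonlinear multiregression model that predicts the distance from the
    stimulating probe to the nerve trunk. Includes a seeded
    phantom simulator of the full bench protocol, k-fold cross-validation
    with correlation-based accuracy and absolute-error metrics, and a
    command-line interface for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
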