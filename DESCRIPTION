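Package: remsefd
Title: REM Sleep Detection from Single-Channel EEG via Spectral Edge
    Frequency Difference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Low-complexity detection of rapid-eye-movement (REM) sleep
    epochs from a single EEG channel. Per 30-s epoch, the difference
    between the 95% and 50% spectral edge frequencies (SEFd) in the
    8-16 Hz band is computed from 2-s subepoch FFT spectra, together
    with absolute and relative band power in decibels. A two-stage
    fixed-threshold classifier marks candidate REM epochs by SEFd and
    confirms them by band power. Includes ROC-based threshold
    calibration with optimal operating-point selection, subject-wise
    cross-validation, evaluation metrics (sensitivity, specificity,
    selectivity, accuracy, Cohen's kappa, per-stage false-positive
    breakdown), EDF/EDF+ signal and hypnogram input, and a synthetic
    stage-labelled EEG generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
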