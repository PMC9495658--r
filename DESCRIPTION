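Package: pulsecal
Title: Cuffless Blood Pressure Estimation from Calibrated Cardiovascular
    Dynamics in the Photoplethysmogram
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates systolic and diastolic blood pressure from a
    single-channel photoplethysmogram (PPG). Detects pulse peaks and
    troughs with a modified Pan-Tompkins scheme, extracts time-domain,
    Lomb-Scargle frequency-domain and nonlinear pulse-rate-variability
    features from the inter-beat-interval series, measures reflective
    pulse transit time (R-PTT) from within-pulse systolic and diastolic
    (reflected-wave) peaks, calibrates a Bramwell-Hill/Moens-Korteweg
    pressure model from a short initial cuff window, and fuses
    model-based estimates with dynamics features in a small neural
    network evaluated by leave-one-subject-out cross-validation.
    Includes a synthetic PPG cohort generator with known ground truth
    and variance-based (Sobol) sensitivity analysis of the calibration
    parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    nnet,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
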