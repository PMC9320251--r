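Package: walkHRV
Title: Heart Rate Variability and Chronotropic Response to a Walking Test
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study the heart-rate response of young, middle-aged,
    frail and non-frail older adults to a moderate (160 m) walking test.
    Provides an integral pulse frequency modulation (IPFM) simulator for
    RR-interval series, walking-test heart-rate trajectories and synthetic
    single-lead ECG; Pan-Tompkins-style R-peak detection with artifact
    flagging, exclusion and cubic-spline correction; time-domain,
    Welch-spectral (LF/HF, normalized units, ECG-derived respiration) and
    non-linear (Poincare SD1/SD2, approximate and sample entropy, short-term
    DFA alpha1) heart-rate-variability indices; chronotropic response
    statistics (time to maximum HR, HRMax, response velocity, percentage
    HR changes between phases); and ROC-based biomarker evaluation with
    orthogonal-distance optimal cut-offs and Wald confidence intervals for
    sensitivity, specificity and predictive values.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'clean.R'
    'detect.R'
    'hrv-nonlinear.R'
    'hrv-spectral.R'
    'hrv-time.R'
    'io.R'
    'pipeline.R'
    'protocol.R'
    'response.R'
    'roc.R'
    'stats.R'
    'synthetic.R'
    'utils.R'
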