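Package: vmatqa
Title: Complexity Metrics, Gamma Analysis and Risk Monitoring for VMAT
    Patient-Specific Quality Assurance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decision support for targeted patient-specific quality assurance
    (PSQA) of volumetric modulated arc therapy (VMAT) plans. Parses DICOM
    RTPLAN control-point sequences, computes ten per-arc aperture and
    modulation complexity metrics, derives per-site percentile specification
    limits in the Lean Six Sigma sense, compares calculated and measured
    planar dose with a gamma-index engine (global dose difference and
    distance-to-agreement), trains a gradient-boosted regressor to predict
    gamma passing rates from 19 plan features, applies defect and at-risk
    flagging rules, and runs an automated end-of-day scan that writes risk
    reports for plans likely to fail PSQA. Includes a synthetic VMAT arc and
    dose-grid generator so the whole pipeline is testable without clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    xgboost,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
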