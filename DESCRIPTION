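Package: pidtrial
Title: PID Treatment-Effect Estimation and Tiered Response Assessment for
    Brain-Tumor Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a tiered radiographic response-assessment workflow in
    neuro-oncology trials: simulation of longitudinal tumor-volume
    trajectories with realistic scan-date jitter and measurement noise,
    per-subject proportional/integral/derivative (PID) treatment-effect
    parameters (tumor burden, tumor control as area under the volume-time
    curve, and linear growth rate) with quadrature on unevenly spaced scans,
    a Cox proportional-hazards model with the three PID terms as
    time-varying covariates (counting-process likelihood, Newton fitting),
    the modified Levin qualitative scoring engine (compartment combination,
    4-week confirmation, progression-free survival derivation,
    score-to-pseudo-volume digitization, synthetic rater), arm-level
    summaries with ROC analysis, and mosaic "flipbook" rendering of
    co-registered volumetric image series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    pROC
Config/testthat/edition: 3
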