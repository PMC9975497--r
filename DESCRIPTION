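Package: stancecurve
Title: Stance-Phase Analysis of Plantar-Pressure Insole Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to extract and characterize the M-shaped vertical
    ground reaction force curve of the gait stance phase from
    pressure-insole force recordings. Provides threshold-based step
    detection with missing-sample gap tolerance, dual-axis normalization
    (force to percent body weight, time to 100 equidistant samples via a
    natural cubic spline), Gaussian-filter based detection and rule-cascade
    disambiguation of the two force maxima and the intervening minimum,
    computation of nine stance-phase curve parameters, per-subject
    ensemble averaging with confidence bands, and forced-entry multiple
    linear regression of the parameters on age, body height, body weight,
    body mass index and handgrip strength. A synthetic cohort generator
    produces insole-like recordings with planted anthropometric effects
    so the full pipeline can be exercised and validated end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
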