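Package: tautr
Title: Spinal Cord Tension Assessment by Ultrasound Shear-Wave Tensography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Desk-scale pipeline for shear-wave tensography of the spinal
    cord: a reduced two-dimensional simulation of acoustic-radiation-force
    induced shear waves in a uniaxially tensioned elastic medium,
    time-to-peak shear wave velocity (SWV) estimation, calibration and
    inversion of the linear squared-SWV versus tension relationship with
    prediction bands, a relative-curvature quality-control metric, and an
    intraoperative diagnostic pipeline (acquisition pooling, fixed-threshold
    classification, Welch and ANOVA/Tukey-Kramer tests, empirical ROC with
    Youden threshold). Includes seeded generators for synthetic tension
    sweeps, clinical-style case series and constructed wave fields.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
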