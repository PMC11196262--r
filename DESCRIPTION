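Package: posturesvr
Title: Postural Stroke-Volume Challenge Analysis for Fluid Responsiveness
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing fluid-responsiveness assessment based on a
    postural stroke-volume challenge in spontaneously breathing,
    hemodynamically stable subjects. Implements the robust
    mean-of-central-five estimator for end-expiratory Doppler velocity-time
    integral (VTImax) readings, symmetric percent-change indices with
    screening and responder thresholds, internal jugular vein collapsibility
    indices, rank-based ROC/AUC diagnostics with Youden cut-off selection,
    and a mechanistic synthetic-cohort generator built on a saturating
    Frank-Starling preload curve that emulates the five-stage upper-body
    elevation / supine / fluid-loading measurement protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
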