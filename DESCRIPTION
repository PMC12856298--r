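Package: pvloop
Title: Pressure-Volume Loop, Myofilament and Molecular Analysis for
    Large-Animal Right-Heart Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for conductance-catheter pressure-volume (PV)
    studies of the right ventricle in large-animal models of chronic
    thromboembolic pulmonary hypertension. Segments beats from multichannel
    hemodynamic recordings, fits end-systolic and end-diastolic PV relations
    across caval-occlusion runs, derives the logistic time constant of
    isovolumic relaxation, and performs conductance calibration (field factor
    and parallel conductance) against thermodilution and hypertonic-saline
    transients. Companion modules fit force-pCa Hill curves and exponential
    sarcomere-length passive-tension relations from skinned-cardiomyocyte
    mechanics, quantify gene expression by the 2^-ddCt method with
    dual-housekeeper normalization, aggregate densitometry and morphometry,
    and provide the study-level statistics layer (normality-dispatched group
    tests, ANCOVA on fit parameters, nested mixed models). A beat-level
    time-varying-elastance simulator with closed-form ground truth makes every
    stage verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    signal,
    jsonlite,
    lme4,
    lmerTest
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
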