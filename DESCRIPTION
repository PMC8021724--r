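Package: simplepda
Title: SIMPLE Clinical Score for Early Prediction of Hemodynamically
    Significant Patent Ductus Arteriosus in ELBW Infants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the SIMPLE score, a 14-item bedside severity score
    (0-29 points) for early, echocardiography-free prediction of
    hemodynamically significant patent ductus arteriosus (hsPDA) in
    extremely low birth weight infants, scored at postnatal 6, 12, 18, 24,
    48 and 72 hours. Provides echocardiographic hsPDA labelling (duct
    diameter/weight > 1.5 mm/kg and/or LA/Ao > 1.5), a calibrated
    synthetic cohort generator for a 48-infant NICU study design,
    diagnostic evaluation (empirical ROC curves, Youden-optimal cut-offs,
    exact Clopper-Pearson confidence intervals, DeLong AUC inference) and
    the nonparametric group-comparison layer (Mann-Whitney U, Fisher
    exact, Pearson chi-square) used in such studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
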