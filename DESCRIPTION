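Package: traumaGrading
Title: Validation Machinery for Polytrauma Risk-Stratification Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to stratify severely injured (polytrauma) patients with four
    published clinical grading systems (CGS, mCGS, PTGS, EAC) from declarative
    threshold definitions, and to validate and compare the scores: strata-wise
    complication odds ratios with confidence intervals, Pearson and
    Yates-corrected chi-square tests, inter-score agreement via Krippendorff's
    alpha, logistic prediction models with ROC/AUC (DeLong intervals), and a
    calibrated synthetic severe-trauma cohort generator with separable early
    (hemorrhage/acid-base) and late (soft-tissue/coagulation) complication
    pathways, so every analysis stage is testable without registry access.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
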