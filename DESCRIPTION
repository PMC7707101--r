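Package: appendiscore
Title: Pediatric Appendicitis Scores, Diagnostic Accuracy, and Score Derivation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements six additive clinical scoring systems for suspected
    pediatric appendicitis (Alvarado, Pediatric Appendicitis Score, Tzanakis,
    Heidelberg Appendicitis Score, modified HAS, and a random-forest derived
    score) as a reusable score engine, together with a full diagnostic-accuracy
    panel (sensitivity, specificity, predictive values, likelihood ratios, and
    ROC-AUC with confidence intervals), a seeded synthetic abdominal-pain
    cohort simulator calibrated to a published two-center cohort of 463
    children, and a from-scratch score-derivation toolkit (CART with
    cost-complexity pruning and a bagged random forest with impurity-based
    feature importance).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    randomForest,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
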