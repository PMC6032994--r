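Package: cbfofknn
Title: Fuzzy k-Nearest Neighbours Tuned by Chaotic Bacterial Foraging
    Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fuzzy k-nearest-neighbour classification (Keller-style
    constrained class memberships and distance-weighted fuzzy voting) with
    automatic tuning of the neighbourhood size k and fuzzy strength m by a
    bacterial foraging optimizer enhanced with chaotic logistic-map
    initialization and adaptive Gaussian mutation of the incumbent best.
    Includes a nested stratified cross-validation pipeline reporting
    accuracy, AUC, sensitivity and specificity per outer fold, a synthetic
    generator for two-class vocal-biomarker-like feature tables with
    correlated feature blocks, and the 23 classical benchmark objectives
    (sphere through Shekel) used to validate the optimizer, together with a
    deterministic grid-plus-polish reference-minimum oracle.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
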