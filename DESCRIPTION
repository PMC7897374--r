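Package: relaxlearn
Title: Relaxometric Learning for NMR T2 Relaxation Curve Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pattern-recognition toolkit for time-domain NMR T2 (CPMG)
    relaxation curves. Classifies raw decay curves with a machine-learning
    framework that combines truncation-based variable optimization (dropping
    long-relaxation-time points), class-balancing bootstrap matrixing,
    repeated double cross-validation around pluggable classifier backends
    (RBF support vector machine, random forest, PLS-DA), and ensemble score
    integration. Includes the upstream compressive-force pipeline that derives
    data-driven hard/tender class labels (exponential force-distance fitting
    plus Ward hierarchical clustering), classification metrics (ROC/AUC,
    per-class correct classification rates, per-variable permutation
    robustness), a synthetic-data generator for multi-exponential decays and
    exponential force curves, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    randomForest,
    jsonlite,
    yaml,
    withr
Suggests:
    mixOmics,
    pROC,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
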