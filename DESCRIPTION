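Package: m7Gsub
Title: Substrate Prediction for N7-Methylguanosine Writers and Readers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Sequence-based prediction of substrates of the
    N7-methylguanosine (m7G) methyltransferase complex (METTL1, WDR4) and
    of the QKI reader isoforms (QKI5, QKI6, QKI7). Implements six RNA
    sequence feature encodings (one-hot, dinucleotide composition,
    accumulated nucleotide frequency, pseudo k-tuple composition, chemical
    property and electron-ion interaction pseudopotential), balanced
    dataset construction with greedy redundancy removal, support vector
    machine models with radial-basis hyperparameter search alongside
    random forest, logistic regression and gradient boosting baselines,
    exhaustive feature-combination and window-length selection,
    cross-prediction matrices between regulators, a synthetic
    motif-planting benchmark generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    e1071,
    randomForest,
    xgboost,
    glmnet,
    jsonlite,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
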