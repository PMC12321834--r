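Package: cmpnntox
Title: Communicative Message Passing Networks for Reproductive Toxicity
    Prediction from SMILES
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts binary reproductive-toxicity labels for small organic
    molecules directly from SMILES strings with a communicative message
    passing neural network (CMPNN): molecules become directed graphs with
    atom and bond feature vectors, node and edge states co-evolve over a
    fixed number of message-passing rounds with an element-wise-maximum
    message booster, and a gated recurrent unit readout produces a
    fixed-length molecular embedding scored by a two-layer head. Ships the
    full training protocol (Adam, linear warm-up then exponential
    learning-rate decay, early stopping on validation AUC), repeated nested
    cross-validation, a classical-metric suite (AUC, accuracy, balanced
    accuracy, sensitivity, specificity, Cohen's kappa, Matthews correlation,
    F1), eleven fingerprint-based baseline classifiers, Morgan/ECFP4
    fingerprints and physicochemical descriptors via OpenBabel, and a
    synthetic-molecule generator with a planted, noisy structure-toxicity
    rule for desk-scale experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
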