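Package: fmll
Title: Federated Multi-Label Learning with Binary Relevance and
    Reduced-Error Pruning Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates federated multi-label classification: a multi-label
    dataset is decomposed by Binary Relevance into one single-target task
    per label, each task is trained on its own client node with a
    reduced-error pruning decision tree (REPTree), and a central server
    aggregates the local trees into a global multi-label predictor.
    Includes CSV/ARFF ingestion for tabular multi-label data, a synthetic
    data generator with planted tree-structured label rules, stratified
    k-fold cross-validation with macro-averaged reports (accuracy,
    precision, recall, F-score, TNR, ROC and PRC areas), baseline
    improvement arithmetic, and Mann-Whitney U and Quade method
    comparison tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    foreign,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
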