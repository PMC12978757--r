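Package: hdec
Title: Subspace-Rotation Ensemble Classification for High-Dimensional Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of wide expression-style matrices (tens to a few
    hundred samples, hundreds to thousands of features) through a staged
    pipeline: min-max normalization, partitioning of the training samples by
    deep fuzzy clustering with a hybrid Gaussian/exponential kernel,
    per-partition feature selection by SVM recursive feature elimination
    hybridized with a modified Fisher score, fusion of the selected features,
    and a random-subspace ensemble whose blocks apply rotation-based
    mixed-space enhancement before heterogeneous base learners (random
    forest, RBF support vector machine, and a weighted-Minkowski
    nearest-neighbour classifier) combined by majority vote. Includes the
    full evaluation harness (confusion-matrix metrics, ROC/AUC, repeated
    stratified splits, sensitivity sweep, ablation variants) and a synthetic
    data generator with known informative features for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    e1071,
    randomForest,
    jsonlite,
    parallel
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
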