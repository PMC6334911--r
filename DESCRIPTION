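Package: tandemfuse
Title: Weighted Fusion of Classifier Probabilities with Differential
    Evolution and Confidence Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines the per-class probability outputs of several
    classifiers into a single weighted soft vote, with the weights
    optimized by a bound-constrained differential evolution search under
    an ordinal squared-distance misclassification penalty.  Includes the
    full Monte-Carlo cross-validation weight-search protocol (repeated
    random splits, subset optimization, selection by complementary-set
    error), confusion-matrix and per-class statistics, pairwise
    classifier agreement (Pearson, Cohen's kappa), patient-level
    recognition rates, and a confidence-threshold sweep that triages
    predictions into trusted and unreliable sets with a Pareto front of
    the coverage/error trade-off.  A synthetic-data generator produces
    labeled probability panels with controlled per-classifier accuracy,
    error correlation, and planted optimal weightings for end-to-end
    testing, and adapters over standard learners let the pipeline run on
    tabular feature data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    randomForest,
    e1071,
    caret,
    glmnet
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
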