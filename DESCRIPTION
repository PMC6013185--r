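Package: omicscreen
Title: Power and Type I Error of Feature-Selection Methods for
    Small-Sample Omics Screens
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation-based evaluation of feature-selection strategies for
    two-group omics screening studies where the sample size is far smaller
    than the number of features. Provides a synthetic-data generator with
    block compound-symmetry correlated features and planted group-mean
    differences, per-feature one-way ANOVA screening with Benjamini-Hochberg
    false discovery rate control, elastic-net penalized logistic regression
    fit by pathwise coordinate descent with cross-validated penalty
    selection, and an experiment harness that estimates power, Type I error,
    and over-selection of correlated null features across a scenario grid.
    The same method roster can be applied to a user-supplied feature table.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
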