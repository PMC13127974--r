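Package: pkboost
Title: Multi-Task Gradient Boosting for Pharmacokinetic Parameter Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint prediction of human clearance (CL) and steady-state volume
    of distribution (VDss) with a multi-task gradient boosting machine whose
    regression trees share their structure across tasks while each leaf holds
    one value per task. Includes a synthetic compound-data generator with a
    shared latent correlation between the two endpoints, preprocessing with
    physiological-range filtering and invertible scaling, supervised
    two-dimensional molecular embeddings (a small convolutional network on
    rendered structure images and a multilayer perceptron on descriptor
    vectors), Boruta-style shadow-feature selection driven by Shapley
    importance, geometric mean fold error and Diebold-Mariano evaluation,
    range-stratified comparisons, repeated-split stability summaries, and
    model-agnostic Shapley attribution with an exact small-dimension oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    ChemmineR,
    ChemmineOB
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
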