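Package: costspace
Title: Cost-Optimal Comparison of Rejection Classifiers Across Clinical Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares any number of binary classifiers with a reject option
    (such as variant pathogenicity predictors) across all possible clinical
    cost scenarios. Implements two expected-cost models: a misclassification-only
    model, whose scenario space is the open unit interval of normalized
    false-positive costs, and a misclassification-plus-rejection model, whose
    scenario space is a triangle in the plane of normalized false-negative and
    false-positive costs. For each model the package computes the exact
    partition of the scenario space into maximal regions where a single
    classifier is cost-optimal: pairwise equal-cost boundary lines are derived
    analytically, their arrangement inside the triangle is built and its faces
    enumerated, faces are assigned a winning classifier and merged into regions
    with area fractions. Also provides estimation of sensitivity, specificity
    and coverage from labeled prediction tables with plug-in score-rejection
    rules, synthetic-data generators, an independent Monte-Carlo winner-counting
    oracle, prevalence sweeps, JSON reporting and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
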