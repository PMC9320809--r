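Package: courtshipSelect
Title: Courtship Ethograms, Behavioral Markov Chains and Divergent Sexual
    Selection Gradients
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative-ethology toolkit for detecting divergent sexual
    selection between Drosophila melanogaster populations. Converts
    state-sampled courtship ethograms (eight behavioral states scored on a
    fixed 10-second grid) into per-trial courtship summaries, tests male
    behavioral plasticity across female genotypes with aligned-rank-transform
    factorial ANOVA, compares courtship sequences as discrete-time Markov
    chains with a likelihood-ratio homogeneity test, normalizes cuticular
    hydrocarbon profiles against an internal standard, and estimates
    standardized selection gradients by exact median (L1) regression with
    bootstrap confidence intervals plus binomial regressions of mating
    success after random-forest variable reduction. A seeded courtship
    simulator with known ground truth makes every estimator verifiable.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    randomForest,
    Rcpp,
    readr,
    rlang,
    stats,
    survival,
    utils
LinkingTo:
    Rcpp
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
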