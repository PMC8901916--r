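Package: suddency
Title: Lehmer Transform, Action Potential Distributions and Suddency-Domain
    EEG Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing positive-valued signals in the domain of
    suddency moments: the Lehmer transform (a ratio of consecutive power sums
    that acts as a statistic-generating function), its analytic first
    derivative, monotone inverse and Lagrange-Buermann series inverse, a
    two-parameter Lambert-W-normalised probability law for suddency moments
    of action potentials with maximum-likelihood fitting, a five-statistic
    per-channel featurizer for multichannel EEG recordings with
    differential-entropy summaries, bagged-decision-tree and
    Gaussian-naive-Bayes classification with replicated stratified
    cross-validation, and seeded generators for synthetic two-class EEG-like
    cohorts with configurable missingness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
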