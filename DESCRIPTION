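Package: recurbayes
Title: Discrete Bayes Decision Rule for Early Cancer Recurrence Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts early (within one year) recurrence of liver cancer from
    categorical laboratory markers with a discrete Bayes decision rule.
    Continuous markers are discretized into physician-defined divisions;
    class-conditional division probabilities use a pattern-dependent shared
    denominator and combine under an independence assumption into posterior
    probabilities for the recurrence and nonrecurrence classes.  Includes
    specificity-constrained optimal marker-subset selection by resampling,
    holdout evaluation with nested training-subset learning curves, a
    diagnostic metric suite (sensitivity, specificity, accuracy, Youden
    index, F1, diagnostic odds ratio), confusion-matrix reconstruction from
    published operating points, a summed-score clinical staging engine with
    the Tokyo Score point table, and a synthetic two-class cohort generator
    for fully reproducible experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
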