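Package: sorsustain
Title: Sustainability Scoring and Text Analysis of State Opioid Response Plans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rubric-based sustainability scoring of State Opioid Response (SOR)
    grant applications, dictionary and stylistic text-feature extraction,
    state-covariate group comparisons with a simulated-null p-p diagnostic,
    cumulative-logit (proportional-odds) and logistic regression screening with
    collinearity pruning and backward stepwise selection, and leave-one-out
    cross-validated document classification (multinomial naive Bayes and
    soft-margin kernel classifiers). Includes a synthetic-data generator that
    emulates the statistical structure of the confidential SOR corpus and of
    state covariate tables so that every pipeline stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    MASS,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
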