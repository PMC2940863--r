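Package: bootscore
Title: Additive Integer Scoring Systems with Bootstrap Confidence
    Intervals for Score-Class Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs additive integer clinical scoring systems from a
    patient cohort table and attaches statistically honest outcome-probability
    estimates to each score. Continuous predictors are dichotomized at the
    ROC point closest to the upper-left corner, screened by the 95% Woolf
    confidence interval of their odds ratio, and combined by a forward
    stepwise algorithm that maximizes the area under the ROC curve and may
    re-enter a variable to give it a larger integer weight. The observed
    outcome proportion of every score class receives a bias-corrected and
    accelerated (BCa) bootstrap confidence interval, and adjacent classes
    with overlapping intervals can be pooled into coarser risk classes.
    A seeded synthetic-cohort generator with fully exposed ground truth
    supports validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
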