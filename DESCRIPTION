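Package: rarliver
Title: Rest-Activity Rhythm Metrics and Survey-Weighted Liver-Function
    Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Derives parametric and non-parametric rest-activity rhythm
    (RAR) metrics from minute-epoch wrist actigraphy and relates them to
    abnormal liver-function biomarkers with survey-weighted regression.
    Includes quality filtering of epoch data (valid-day and
    valid-participant rules), fitting of the sigmoidally-transformed
    extended cosine model with its pseudo-F rhythmicity statistic,
    interdaily stability, intradaily variability and the L5 midpoint,
    weighted quintile scoring with impaired-rhythmicity and
    abnormal-biomarker composites, an auditable exclusion cascade, a
    battery of weighted logistic, log-linear and ordinal models with
    trend, interaction and stratified variants, and a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    stats,
    minpack.lm,
    sandwich,
    MASS,
    foreign,
    generics,
    withr
Suggests:
    testthat (>= 3.0.0),
    haven,
    jsonlite,
    optparse
Config/testthat/edition: 3
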