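Package: worklife
Title: Multistate Working Life Expectancy from Longitudinal Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates expected years of employment, joblessness, and retirement
    between a baseline and a censoring age from long-format longitudinal panel
    data, using a multistate life-table approach. Gender-stratified discrete-time
    multinomial logistic transition models with restricted-cubic-spline age
    effects and education-by-parity interactions are fitted to person-period
    transition records; age-specific transition-probability matrices predicted at
    covariate profiles are assembled into an age-expanded absorbing Markov chain
    whose fundamental matrix yields state expectancies. Model-implied mortality
    can be matched to an external period life table, and percentile bootstrap
    confidence intervals are obtained by resampling persons with replacement
    while preserving each person's full trajectory. A synthetic-panel generator
    with a known ground-truth transition model supports testing and recovery
    studies without access to register or survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    nnet,
    splines,
    jsonlite
Config/testthat/edition: 3
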