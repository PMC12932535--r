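Package: coordeval
Title: Norm-Referenced Evaluation of Coordination Ability in Preschool Children
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Construction and application of a norm-referenced evaluation
    instrument for the coordination ability of children aged 4.0-5.9 years.
    Implements multi-method indicator weighting (analytic hierarchy process
    with consistency testing, correlation-matrix principal component
    weighting, coefficient-of-variation weighting), five-level percentile
    norm bands with a P3 no-score floor, weighted composite scoring and
    four-band classification, 80/20 back-testing validation with Wilson
    confidence intervals, supporting psychometric statistics (test-retest
    correlation, ICC(2,1), Cronbach's alpha, McDonald's omega, Kendall's W,
    Delphi consensus statistics), sex and age group comparisons with Cohen's
    d, and a synthetic-cohort generator emulating the instrument's reference
    population.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
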