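Package: gabkit
Title: Psychometric Validation Toolkit for a Three-Module Adolescent
    Gender-Stereotype Battery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scoring, reliability, ordinal factor analysis, known-groups and
    criterion validity, response-style screening, self-attribution bias
    decomposition, and norm construction for a three-module adolescent
    gender-stereotype battery (a 4-point attitude scale and two trichotomous
    attribution scales). Implements categorical scoring schemas with empirical
    stereotype-direction verification, polychoric correlations with principal
    axis factoring and direct oblimin rotation, parallel analysis, Cronbach's
    alpha with Feldt intervals, McDonald's omega via the Schmid-Leiman
    decomposition, Games-Howell post hoc tests, gender-balanced weighted norms
    with percentile and kernel-density (antimode) cutoffs, a dip statistic for
    unimodality, and gender-stratified correlation analysis with a
    Simpson's-paradox diagnosis. A seeded synthetic-cohort generator with the
    statistical structure of the validation study makes every stage testable
    end to end.
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
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
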