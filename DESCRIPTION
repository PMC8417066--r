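Package: wordfx
Title: Screening Wording Effects in Mixed-Worded Likert Scales with
    Constrained Factor Mixture Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and screens out respondents who answer positively and
    negatively worded items of the same scale inconsistently. Implements two
    constrained two-class factor mixture models (a sign-flipped-loadings
    parameterization and a random-intercept +/-1 parameterization) estimated
    by multistart EM with equality and sign constraints, together with the
    downstream validation toolkit: two-step polychoric correlations with
    positive semi-definite smoothing, permutation-based parallel analysis on
    polychoric matrices, least-squares confirmatory factor models (one
    factor, two correlated factors, random-intercept item factor analysis,
    each with an optional error correlation), modification indices with
    standardized expected parameter change, categorical (ordinal) omega and
    alpha reliability with BCa bootstrap intervals, latent class profile
    comparisons, and a synthetic-data generator with a planted inconsistent
    class for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    boot,
    jsonlite,
    numDeriv
Suggests:
    knitr,
    MASS,
    mvtnorm,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
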