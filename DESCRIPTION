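Package: deltarel
Title: Multinomial Delta-Method Standard Errors for Reliability Coefficients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic nonparametric standard errors and Wald confidence
    intervals for the coefficients reported in a classical-test-theory
    reliability analysis: item and scale means, variances, standard
    deviations, inter-item covariances and correlations, item-rest
    correlations, the split-half coefficient, and Guttman's lambda-1,
    lambda-2 and lambda-3 (Cronbach's alpha).  Standard errors are derived
    under multinomial sampling of response patterns by a two-step
    procedure: coefficients are expressed as generalized exp-log chains of
    design matrices and elementwise transforms, Jacobians follow from the
    chain rule, and the delta method yields the asymptotic variance.
    Closed-form standard errors are provided alongside the generic engine,
    together with normal-theory and F-based benchmark intervals, an item
    response theory (two-dimensional five-parameter acceleration model)
    data simulator, and a simulation harness reporting scaled bias and
    coverage against Agresti-Coull bands.
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
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
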