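Package: momentbf
Title: Bayes Factors with Effect-Size and Moment Priors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bayes factors for t tests, multiple regression and ANOVA model
    comparisons under effect-size priors (equal-weight mixtures of two shifted
    scaled t distributions focused on a prespecified Cohen's d) and nonlocal
    moment priors (d-squared-weighted t densities with zero mass at the null),
    together with the scaled-Cauchy (JZS) default prior as a special case.
    All Bayes factors are one-dimensional integrals of noncentral t, F or
    chi-squared density ratios against an effect-size prior and depend on the
    data only through the test statistic; a generic test-statistic-based
    engine extends the approach to any test with a known noncentral sampling
    distribution, including chi-squared tests with a Gamma prior on Cohen's
    w squared.  Includes recommended hyperparameters, conversions between
    F, partial R-squared and partial eta-squared, significance-outcome Bayes
    factors, design-evaluation curves, a synthetic-data fixture generator,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    generics,
    tibble,
    jsonlite,
    yaml,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
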