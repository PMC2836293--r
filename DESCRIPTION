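Package: geotol
Title: Tolerance Intervals and Regions for Geocoding Positional Errors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the positional accuracy of automated
    street geocoding. Provides a seeded synthetic generator of geocoding
    error vectors with street-orientation-aligned anisotropy and
    covariate-dependent lognormal magnitudes; regression and ANOVA analyses
    of covariate effects on log error magnitude; pointwise confidence
    intervals and one-sided upper tolerance bounds for error magnitudes via
    the noncentral t construction; and bivariate elliptical tolerance
    regions, both normality-based (chi-square calibrated) and nonparametric
    (minimum-volume ellipse approximated by subsample resampling). A
    pipeline function reproduces the full descriptive, regression and
    tolerance analysis from a single seeded configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
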