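Package: growmort
Title: Size-Standardized Growth-Mortality Trade-Off Analysis for Seedling Censuses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits power-law nonlinear mixed-effects growth models to repeated
    seedling diameter measurements, computes size-specific relative growth
    rates at a common reference size, models interval-censored mortality with
    a binomial complementary log-log mixed model and log-interval offset, and
    quantifies cross-species trait-demography relationships with Pearson
    correlations and standardized major axis regression. Includes a
    synthetic census generator with known truth for parameter-recovery
    testing and an end-to-end reproducible pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    MASS,
    nlme,
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
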