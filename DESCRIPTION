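Package: kpsae
Title: Small-Area Estimation of Key-Population Sizes from Sparse Multiplier Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the size of hard-to-reach key populations (such as gay men
    and other men who have sex with men) in subnational areas from a handful of
    survey-based direct estimates. Implements respondent-driven-sampling (RDS-II)
    multiplier direct estimation, heteroscedastic log-fraction regression with
    confidence-interval-derived variances, Gaussian-process kriging imputation of
    missing HIV prevalence, a joint hierarchical Bayesian model sampled by adaptive
    Metropolis-within-Gibbs, and composition-sampling posterior prediction with
    leverage and relative-width diagnostics. Includes a synthetic-data generator
    emulating the study design so every stage is testable without restricted
    survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
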