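Package: ppiscale
Title: Model-Based Measurement of Prepulse Inhibition of the Acoustic Startle Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a sigmoid baseline startle curve that is jointly scaled
    along the startle axis (startle scaling, alpha) and the sound axis
    (sound scaling, beta) by each prepulse condition, replacing the
    traditional PPI ratio with a formal model of prepulse inhibition.
    Includes trial-level preprocessing of accelerometer startle data
    (z-score normalization, log-scale movement summaries, distributional
    screening), bounded nonlinear least-squares fitting with trial-level
    cross-validation, parameter-swap and jittered-refit uncertainty
    analyses, group comparison machinery (linear discriminant analysis
    with permutation tests, PCA, scaling-versus-baseline correlations,
    baseline-adjusted ANCOVA, a bootstrapped ratio test for multiplicity),
    and a synthetic startle-data generator with correlated animal-level
    parameters and log-normal trial noise.
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
    minpack.lm,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
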