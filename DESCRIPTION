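Package: agrovar
Title: Variance Decomposition and Power Analysis for Agroinfiltration
    Transient Expression Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and planning around the variability of
    transient expression assays in Nicotiana benthamiana leaves. Provides a
    tidy disk-level data model with quality-control filters for plate-reader
    fluorescence, a hierarchical location-scale mixed model that attributes
    observed variance to batch-level means and standard deviations,
    plant-level means and standard deviations, and disk-level noise,
    evaluation of ratiometric (reporter/normalizer) normalization schemes via
    per-plant coefficients of variation with one-tailed Welch tests and
    Bonferroni correction, between-replicate reproducibility metrics
    (empirical CDFs, one-sample Kolmogorov-Smirnov statistics, 1-D
    Wasserstein distance), and a Monte Carlo power-analysis engine that
    estimates the minimum number of plants needed to detect a given effect
    size, with exponential-decay summaries of the resulting power curves.
    A seeded synthetic-data generator reproduces the nested
    batch/plant/disk structure, including random effects on both level means
    and level standard deviations and dual correlated fluorescence channels,
    so the full pipeline is testable without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    minpack.lm,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
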