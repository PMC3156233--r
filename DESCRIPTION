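Package: survassay
Title: Survival Analysis for Lifespan Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Survival analysis toolkit for lifespan assays in aging
    research. Reads grouped lifespan tables (tab-separated blocks headed
    by a "%" identifier line), computes Kaplan-Meier estimates with
    Greenwood variances, restricted mean lifespan and mortality
    percentiles, and log cumulative hazard curves. Provides two-sample
    tests for differences in lifespan length (log-rank,
    Fleming-Harrington weighted log-rank, Fisher's exact test at a
    mortality quantile), in survival-curve shape (permutation
    Kolmogorov-Smirnov, Neyman's smooth test with data-driven dimension,
    Chow test on log cumulative hazard regressions), and in lifespan
    variance (survival-time F-test with a Shapiro-Wilk normality gate,
    partial-slopes rank-sum test, normalized Chow test), plus Cox
    proportional-hazards regression with model-based and robust standard
    errors, pairwise comparison reports with Bonferroni correction, and a
    synthetic lifespan simulator for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    flexsurv,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse
Config/testthat/edition: 3
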