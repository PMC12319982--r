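Package: microdev
Title: Longitudinal EEG Microstate Segmentation and Developmental Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Polarity-invariant microstate analysis of resting-state EEG with a
    longitudinal modelling layer. Implements global field power (GFP) peak
    extraction, modified k-means clustering of peak topographies, fit criteria
    (global explained variance and the cross-validation criterion) over a range
    of cluster numbers, backfitting with minimum-duration label smoothing, the
    four canonical microstate statistics (duration, occurrence, coverage, GEV),
    canonical-class template matching, per-group outlier trimming, and
    random-intercept linear mixed models of feature trajectories with
    BIC-gated selection among linear, quadratic and logarithmic age terms and
    Cohen's f-squared effect sizes. A synthetic-data module generates EEG with
    planted microstate structure and longitudinal feature tables with known
    effects so that every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
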