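Package: ctgdss
Title: Cardiotocography Decision Support for Hypoxic-Ischemic Encephalopathy Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying intrapartum decision support built on labeled
    cardiotocography (CTG) event streams. Provides a synthetic cohort generator
    with semi-Markov fetal heart rate and uterine pressure event dynamics,
    delivery-anchored 20-minute epoch segmentation with validity filtering,
    transition-count and dwell-time featurization, parity-aware random-forest
    epoch classifiers with per-tree class-balanced undersampling and out-of-bag
    posteriors, a sliding-window intervention recommendation rule calibrated to
    the healthy-group Caesarean delivery rate, and cohort statistics (relative
    risks with Katz confidence intervals, chi-square tests, notch-style median
    confidence intervals, and replicated system comparisons).
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
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
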