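Package: hsasca
Title: Hybrid Self-Adaptive Sine Cosine Optimization for Boosted-Tree
    Air-Quality Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-based metaheuristic hyperparameter tuning for
    gradient-boosted regression trees, built around a hybrid self-adaptive
    sine cosine algorithm (HSA-SCA) that switches from sine-cosine
    exploration to firefly-style exploitation late in the run. Includes the
    full multi-run comparison protocol (per-run summaries, Levene,
    Shapiro-Wilk and paired-t significance chain), Shapley-value model
    interpretation with per-prediction relative attributions, and a seeded
    synthetic generator for daily benzo(a)pyrene monitoring data with
    seasonal pollutant structure, so the whole pipeline is testable without
    the original monitoring records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
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
    withr,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
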