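Package: segrater
Title: Linking Segmentation Quality Metrics to Surgeon Ratings of Video Overlays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluation pipeline for multi-class semantic segmentation of
    surgical video against human observer ratings. Provides a battery of
    overlap, boundary-distance, temporal-stability and error-specific metrics
    over per-frame label maps, weighted temporal smoothing of predictions,
    expertise-stratified absolute Spearman correlation of metrics against
    Likert ratings, class-wise correlation tables with small-class exclusion,
    and bootstrap ranking-stability analysis. A synthetic module generates
    reference sequences, controlled mask degradations (boundary overreach,
    flicker, hallucination, mislabeling) and simulated rater panels so the
    full study runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    png,
    withr,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
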