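# segrater

Which segmentation quality metrics actually agree with the surgeons who use
the overlays?

Deep-learning models that segment anatomical structures in surgical video are
routinely benchmarked with overlap scores such as the Dice coefficient, but a
high Dice score does not guarantee that an overlay is *perceived* as accurate
or useful in the operating room — and some failure modes surgeons care about
(flicker, hallucinated structures, boundaries creeping over dissection
planes) are invisible to frame-wise overlap. `segrater` implements the
evaluation pipeline for studying this question: a multi-family metric battery
over multi-class label-map video, weighted temporal smoothing of predictions,
expertise-stratified correlation of metrics against observer ratings,
class-wise analysis with small-class exclusion, and bootstrap
ranking-stability analysis. A synthetic module generates reference clips,
controlled prediction degradations and simulated rater panels, so the entire
study runs end to end with no external data.

It is aimed at researchers validating segmentation models for intraoperative
guidance, and more generally at anyone relating pixel-level quality metrics
to ordinal human ratings.

## The computation

**Metric battery.** For each sample — one anatomical structure in one video —
per-frame binary-mask metrics are averaged over the frames where the
structure appears in the reference or the prediction:

- *Overlap*: Dice `2TP/(2TP+FP+FN)`, IoU `TP/(TP+FP+FN)`, and the
  F<sub>β</sub> score `(1+β²)TP / ((1+β²)TP + β²FN + FP)` (default β = 2,
  emphasizing recall).
- *Boundary distance*: Hausdorff distance (percentile-configurable), average
  symmetric surface distance (ASSD), normalized surface Dice at tolerance τ,
  and boundary IoU within a band of width *d* — all on 4-connected
  boundaries with exact Euclidean distances.
- *Error-specific*: sensitivity, specificity, FPR, FNR.
- *Temporal*: frame-to-frame self-IoU (temporal consistency), normalized
  pixel-count variation, and the standard deviation of per-frame IoU over a
  sliding 10-frame window.

**Temporal smoothing.** Predictions can be smoothed with the causal weighted
average `F̂_t = Σ_{k=0..9} w_k F_{t−k}` with `w_k = 1.0 − 0.1·k`, normalized
by the weights used and followed by a per-pixel argmax.

**Observer analysis.** Per-sample mean ratings (a 1–5 Likert accuracy item)
are correlated with each metric using the absolute Spearman rank correlation
|ρ| — absolute, because error and distance metrics are negatively oriented.
Raters are stratified by experience: *expert* (> 100 cases performed),
*intermediate* (> 10 performed or assisted, ≤ 100 performed), *novice*
(≤ 10 performed and assisted). Ranking stability is assessed by drawing
1000 subsamples of 35 of the 46 samples, re-ranking metrics by |ρ| on each,
and summarizing the rank distribution (median rank, ties broken by mean
rank).

## Worked example

```r
library(segrater)
library(dplyr)

config <- default_study_config(seed = 1)   # 12 clips, 46 samples, 26 raters
study  <- generate_study(config)           # simulate + degrade + evaluate
study
#> <segrater_study: 12 videos, 46 samples, dice 0.26-0.94>

ratings <- simulate_ratings(study$quality, config$raters, config$eval, seed = 1)
corr <- correlation_table(study$metrics, ratings, config = config$eval)
corr |>
  filter(metric %in% c("dice", "f_beta", "assd", "temporal_consistency")) |>
  tidyr::pivot_wider(id_cols = metric, names_from = group, values_from = abs_rho)
#>   metric                 all expert intermediate novice
#> 1 dice                  0.99   0.97         0.96   0.87
#> 2 f_beta                0.9    0.87         0.89   0.8
#> 3 assd                  0.7    0.67         0.68   0.65
#> 4 temporal_consistency  0.81   0.79         0.78   0.7

ranks <- bootstrap_ranks(study$metrics, aggregate_ratings(ratings, "all"),
                         stability_config(rng_seed = 1))
head(order_metrics(ranks), 5)
#> [1] "dice" "iou" "f_beta" "temporal_consistency" "pixel_count_variation"

usefulness_accuracy_pearson(ratings)
#> [1] 0.98
```

Reading the output: overlap metrics track the simulated surgeons' ratings
most closely (|ρ| ≈ 0.99 over all 26 raters), distance metrics only
moderately (ASSD ≈ 0.70), and the novice stratum correlates consistently
less than the expert stratum while rating more leniently — the qualitative
pattern the rater model encodes. The bootstrap ranking confirms Dice/IoU as
the stably best-ranked metrics, and per-video mean accuracy and
identification-improvement ratings are strongly Pearson-correlated.

`run_pipeline(config, output_dir = "run")` performs all of the above and
writes frame manifests, `metrics.csv`, `ratings.csv`, `correlations.csv`,
`correlations_by_class.csv`, `ranks.csv` and a run manifest; identical
config and seed give byte-identical outputs. `autoplot()` methods draw the
correlation heat-map and the ranking-stability dot plot.

## Vignette

`vignettes/observer-study.Rmd` documents the models and their assumptions,
every tunable parameter with its default and rationale, what the synthetic
generator does and does not emulate, and known limitations.
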