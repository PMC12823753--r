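---
title: "Relating segmentation metrics to observer ratings: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relating segmentation metrics to observer ratings: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segrater)
```

## The problem

Segmentation models for intraoperative guidance render colored overlays of
anatomical structures (airways, aorta, nerves, pericardium, ...) on live
surgical video. Benchmarks score such models with pixel-overlap statistics,
but clinical acceptability is a perceptual judgement made by surgeons, and
the two need not agree: a model can score a high Dice while flickering
distractingly, hallucinating structures, or bleeding across dissection
planes. `segrater` implements the computational side of an observer study
that quantifies the agreement — a battery of quality metrics per (video,
structure) sample, correlated against ordinal ratings from observers of
varying surgical experience — together with a synthetic data module that
stands in for the video material and the rater panel.

## The metric battery

Every metric is computed per sample, i.e. per structure within one video
clip, from binary per-frame masks.

**Frame-presence rule.** A frame contributes to a sample's frame-metric
average iff the structure appears in the reference *or* the prediction in
that frame. Long stretches where the structure is legitimately absent would
otherwise dilute every average toward its degenerate value.

**Degenerate frames.** When exactly one mask is empty, overlap metrics
(Dice, IoU, F-beta, NSD, boundary IoU) are 0, sensitivity is 0 when the
reference is non-empty, and the surface-distance metrics are assigned the
frame diagonal `sqrt(H^2 + W^2)` — a bounded penalty that keeps per-sample
averages finite while still punishing total misses. Rates with a zero
denominator (e.g. sensitivity when the structure is absent from the
reference) are undefined for that frame and skipped, never coerced to a
number. When both masks are empty the frame is skipped entirely.

**Distance machinery.** Boundaries use 4-connectivity (a mask pixel with
any 4-neighbor outside the mask, frame edge counting as outside); distances
are exact Euclidean pixel distances, computed in double precision as
pairwise minima over boundary-pixel sets. This fixes the conventions tightly
enough that brute-force enumeration oracles agree to machine precision,
which is how the test suite validates the whole family (Hausdorff, ASSD,
normalized surface Dice, boundary IoU).

**Temporal metrics.** `temporal_consistency` is deliberately
reference-free: it is the mean IoU between consecutive *predicted* masks,
because flicker is a property of the displayed overlay itself; the
reference-dependent notion of temporal quality is covered separately by
`iou_window_variation` (windowed standard deviation of per-frame IoU).
`pixel_count_variation` normalizes the mean absolute frame-to-frame count
change by the mean count, so structure size cancels.

### Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `f_beta` | 2 | recall-weighted F-score; β > 1 because missing a structure is costlier than over-painting it |
| `nsd_tolerance_px` | 2 px | boundary deviation considered clinically negligible |
| `boundary_band_px` | 2 px | band width isolating boundary agreement in boundary IoU |
| `hausdorff_percentile` | 100 | classical maximum; 95 gives the robust variant |
| `smoothing_window` | 10 frames | length of the causal average window |
| `temporal_window` | 10 frames | window of the IoU-variation metric |
| `likert_min`, `likert_max` | 1, 5 | rating scale; a standard 5-point survey scale. All downstream analysis is rank-based, so the scale choice does not affect Spearman results |
| `min_class_samples` | 3 | smallest class entering the class-wise tables; one- and two-sample classes produce artificially perfect correlations |

The distance-family defaults (β, τ, band width, percentile) are common
choices in segmentation benchmarking; all are surfaced in `eval_config()`
rather than hard-coded.

## Temporal smoothing

Predictions are smoothed with the causal weighted average
\[
\hat F_t = \sum_{k=0}^{\min(K-1,\,t)} w_k\, F_{t-k},\qquad w_k = 1.0 - 0.1\,k
\;\; (K = 10),
\]
followed by a per-pixel argmax over classes. Two numerical choices were
genuinely open:

* **Normalization.** The weights sum to 5.5 and argmax is scale-invariant,
  so for full windows normalization is irrelevant; we divide by the sum of
  the weights actually used so that the truncated start-up frames live on
  the same score scale.
* **Start-up.** For `t < K` the window is truncated, not padded: no frames
  exist before the first, and zero-padding would bias early frames toward
  background.
* **Ties.** Argmax ties break toward the lowest class index (background
  first), a deterministic rule asserted in the tests.

The smoother accepts any non-negative score field (softmax probabilities,
shifted logits, one-hot labels); hard label maps are one-hot encoded first.
For window lengths other than 10 the taper generalizes to `w_k = 1 − k/K`.

## Observer analysis

Ratings are averaged per sample *before* correlating (one mean rating per
sample, not per-rater correlations averaged), and the comparison uses the
absolute Spearman coefficient because the battery mixes positively and
negatively oriented metrics. Undefined correlations — a metric constant
across the sample set — are reported as missing, never as zero: a constant
metric carries no ranking information, which is categorically different
from evidence of zero association.

Experience strata: expert (> 100 cases performed), intermediate (> 10
performed or assisted, ≤ 100 performed), novice (≤ 10 both). The precedence
expert → intermediate → novice makes the partition total and unique. The
"all" group is the pooled mean over all participants (not the mean of group
means), weighting each rater equally.

Ranking stability draws `m = 35` of the 46 samples *without* replacement
(subsets of distinct samples, matching the stated subsample size) 1000
times, re-ranks metrics by |ρ| within each draw (average ranks on ties; an
undefined |ρ| gets the replicate's worst rank), and orders metrics by median
rank with mean-rank tie-break, then lexicographically for full determinism.

## The synthetic study

The generator emulates the *structure* of the study material, not its
appearance: 12 clips of 64×64 frames (30 frames each by default), 46
(video, structure) samples over 8 anatomical structure classes with
realistic relative sizes — from a 3 px thoracic duct to a 13 px lung — and
an allocation in which common structures appear in every clip while the
esophagus and thoracic duct occur only once and twice, so the small-class
exclusion path is exercised by construction. Each structure is an
ellipse-like blob on a seeded random walk; blob placement rejects positions
that would bury an already-placed structure, keeping occlusion partial.

Predictions are built by degrading the reference with the error modes
observers describe: boundary over/under-segmentation (morphological
dilation/erosion, via EBImage), spatial offset, per-frame boundary jitter,
flicker dropout, hallucinated components of the same class inserted away
from the true structure (disk of half the structure radius), and systematic
relabeling as another class. A severity ladder spread evenly over the 46
samples and cycled through five mode mixtures grades quality across samples
(per-sample Dice spanning roughly 0.2–0.95); erosion and offsets are capped
relative to the structure radius so heavy settings corrupt small structures
without annihilating them.

The rater model maps a sample's latent quality `q ∈ [0, 1]` to a Likert
rating: `clamp(round(L_min + (L_max − L_min)(leniency + sensitivity·q) + ε))`
with `ε ~ N(0, noise_sd)`. Latent quality is the sample's Dice score, which
makes parameter recovery well-posed (the overlap family should then
correlate best, and stratified correlations should order by group
sensitivity). The default panel is 7 experts (sensitivity 1.0, leniency 0,
noise 0.08), 11 intermediates (0.7, 0.25, 0.15) and 8 novices (0.4, 0.5,
0.2): novices rate higher on average and track quality less closely,
compressing their score range. The intermediate parameters are interpolated
between the two anchored groups.

What the generator does **not** emulate: appearance (texture, lighting,
occlusion by instruments), annotation ambiguity in the reference,
rater-specific bias structure (each rater draws from the group model
independently), correlations between error modes, and class-dependent rater
attention. Consequently, passing tests show that the *pipeline* recovers
the patterns its inputs encode — not that any particular metric is
clinically superior on real surgical video.

## Replication design and problem sizes

The study material (scenes and degradations) defines the 46 samples and is
held fixed, mirroring a survey in which one fixed set of overlays is shown
to every participant; replication varies the rater panel. The
observer-pattern checks therefore resimulate 100 rater panels over one
generated study and count how often the expert-group |ρ(dice)| exceeds the
novice-group value and how often novice mean ratings exceed expert means.
Default sizes — 30 frames per clip, 64×64 px, 1000 bootstrap replicates,
100 rater panels — were chosen so per-sample frame averages and rank
distributions are well estimated while a full run stays interactive
(seconds to a few tens of seconds per stage).

## Known limitations

* Metrics are 2-D and semantic only: no volumetric variants, no
  instance-level matching of connected components.
* The distance machinery is exact but quadratic in boundary size; it is
  sized for clip-scale evaluation, not whole-slide masks.
* The empty-mask diagonal penalty bounds, but distorts, distance averages
  for samples with many total-miss frames; comparisons across samples with
  very different miss rates should prefer overlap metrics.
* Simulated raters cannot validate rating-scale anchors or inter-rater
  reliability; those require a real observer study.
* Spearman correlations are reported without significance tests or
  confidence intervals; the bootstrap ranking addresses stability, not
  inference.
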