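#' Evaluation configuration
#'
#' Collects every tunable of the metric battery and the rating scale in one
#' place. Defaults follow common practice in segmentation benchmarking and a
#' standard 5-point Likert survey scale; all of them can be overridden here
#' or from a YAML/JSON config file via [read_pipeline_config()].
#'
#' @param f_beta Positive weight `beta` of the F-beta score; `beta > 1`
#'   emphasizes recall over precision. Default 2.
#' @param nsd_tolerance_px Tolerance `tau` (pixels) of the normalized surface
#'   Dice: boundary points within `tau` of the other boundary count as
#'   matched. Default 2.
#' @param boundary_band_px Band width `d` (pixels) of the boundary IoU.
#'   Default 2.
#' @param hausdorff_percentile Percentile of directed surface distances used
#'   by the Hausdorff statistic; 100 is the classical maximum. Default 100.
#' @param smoothing_window Window length `K` of the weighted temporal average.
#'   Default 10.
#' @param temporal_window Window length of the IoU-variation temporal metric.
#'   Default 10.
#' @param likert_min,likert_max Integer bounds of the rating scale.
#'   Default 1 and 5.
#' @param rng_seed Integer seed used by stages that consume randomness.
#' @param min_class_samples Minimum number of per-class samples required for a
#'   structure to enter the class-wise correlation table; smaller classes are
#'   excluded (and reported) because correlations over one or two samples are
#'   artificially perfect. Default 3.
#'
#' @return An object of class `eval_config` (a named list).
#' @export
eval_config <- function(f_beta = 2, nsd_tolerance_px = 2, boundary_band_px = 2L,
                        hausdorff_percentile = 100, smoothing_window = 10L,
                        temporal_window = 10L,
                        likert_min = 1L, likert_max = 5L, rng_seed = 1L,
                        min_class_samples = 3L) {
  stopifnot(f_beta > 0, nsd_tolerance_px > 0, boundary_band_px >= 1,
            hausdorff_percentile > 0, hausdorff_percentile <= 100,
            smoothing_window >= 1, temporal_window >= 2,
            likert_min < likert_max, min_class_samples >= 1)
  structure(
    list(f_beta = f_beta, nsd_tolerance_px = nsd_tolerance_px,
         boundary_band_px = as.integer(boundary_band_px),
         hausdorff_percentile = hausdorff_percentile,
         smoothing_window = as.integer(smoothing_window),
         temporal_window = as.integer(temporal_window),
         likert_min = as.integer(likert_min),
         likert_max = as.integer(likert_max),
         rng_seed = as.integer(rng_seed),
         min_class_samples = as.integer(min_class_samples)),
    class = "eval_config"
  )
}

# Derive a per-stage 32-bit seed from the study seed; keyed by stage name so
# one knob reproduces the whole pipeline without coupling stages.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483587)
}
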