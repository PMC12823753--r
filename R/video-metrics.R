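#' Temporal consistency of a predicted structure
#'
#' Reference-free flicker measure: the mean IoU between consecutive frames of
#' the prediction's own binary mask. A rock-stable overlay scores 1; an
#' overlay that appears and disappears every frame scores 0. Frame pairs
#' where the structure is absent from both frames carry no information and
#' are skipped; pairs where it is present in exactly one frame contribute 0.
#'
#' @param pred A [label_sequence()] with at least 2 frames.
#' @param structure Structure (class) name.
#' @return Value in `[0, 1]`, or `NA` if the structure is never predicted.
#' @export
temporal_consistency <- function(pred, structure) {
  tt <- n_frames(pred)
  if (tt < 2L) stop("temporal consistency needs at least 2 frames", call. = FALSE)
  vals <- numeric(0)
  prev <- structure_mask(pred, structure, 1L)
  for (t in 2:tt) {
    cur <- structure_mask(pred, structure, t)
    if (any(prev) || any(cur)) {
      vals <- c(vals, iou(confusion_counts(cur, prev)))
    }
    prev <- cur
  }
  if (length(vals) == 0L) NA_real_ else mean(vals)
}

#' Pixel-count variation over time
#'
#' Mean absolute frame-to-frame change in the predicted pixel count of a
#' structure, normalized by the mean count (`max(1, mean)` guards the
#' never-predicted case). 0 for a constant-size overlay; large values signal
#' high-frequency size flicker. Lower is better.
#'
#' @inheritParams temporal_consistency
#' @return Non-negative real.
#' @export
pixel_count_variation <- function(pred, structure) {
  tt <- n_frames(pred)
  if (tt < 2L) stop("pixel-count variation needs at least 2 frames", call. = FALSE)
  id <- match(structure, pred$class_names) - 1L
  if (is.na(id)) stop("unknown structure: ", structure, call. = FALSE)
  n_t <- vapply(seq_len(tt), function(t) sum(pred$frames[, , t] == id), numeric(1))
  mean(abs(diff(n_t))) / max(1, mean(n_t))
}

# Population standard deviation.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' IoU variation over a sliding window
#'
#' Per-frame IoU against the reference is computed for the structure
#' (frames where the structure is absent from both sequences are skipped),
#' then the population standard deviation is taken within each sliding
#' window (stride 1) and averaged over windows. Captures low-frequency
#' quality drift as opposed to the frame-to-frame flicker measured by
#' [temporal_consistency()]. Windows are truncated to the number of frames
#' with defined IoU when the clip is shorter than the window.
#'
#' @param pred,ref [label_sequence()] objects sharing `T`, `H`, `W` and
#'   class names.
#' @param structure Structure name.
#' @param window Window length (default 10 frames).
#' @return Non-negative real; `NA` when fewer than 2 frames have defined IoU.
#' @export
iou_window_variation <- function(pred, ref, structure, window = 10L) {
  stopifnot(window >= 2)
  tt <- n_frames(pred)
  if (tt != n_frames(ref)) stop("sequences differ in length", call. = FALSE)
  vals <- vapply(seq_len(tt), function(t) {
    pm <- structure_mask(pred, structure, t)
    rm <- structure_mask(ref, structure, t)
    if (!any(pm) && !any(rm)) NA_real_ else iou(confusion_counts(pm, rm))
  }, numeric(1))
  vals <- vals[!is.na(vals)]
  if (length(vals) < 2L) return(NA_real_)
  w <- min(window, length(vals))
  starts <- seq_len(length(vals) - w + 1L)
  mean(vapply(starts, function(s) sd_pop(vals[s:(s + w - 1L)]), numeric(1)))
}

metric_names <- c("dice", "iou", "f_beta", "nsd", "boundary_iou",
                  "hausdorff", "assd",
                  "sensitivity", "specificity", "fpr", "fnr",
                  "temporal_consistency", "pixel_count_variation",
                  "iou_window_variation")

# Full frame-level battery for one (pred, ref) mask pair. Degenerate frames:
# exactly one empty mask -> overlap family 0, distances = frame diagonal
# (bounded total-miss penalty), rates from counts (NA where 0/0).
frame_battery <- function(pm, rm, config) {
  cc <- confusion_counts(pm, rm)
  er <- error_rates(cc)
  out <- c(dice = dice(cc), iou = iou(cc),
           f_beta = f_beta(cc, config$f_beta),
           nsd = NA_real_, boundary_iou = NA_real_,
           hausdorff = NA_real_, assd = NA_real_,
           sensitivity = er$sensitivity, specificity = er$specificity,
           fpr = er$fpr, fnr = er$fnr)
  if (any(pm) && any(rm)) {
    sdist <- surface_distances(pm, rm)
    out["nsd"] <- nsd(sdist, config$nsd_tolerance_px)
    out["boundary_iou"] <- boundary_iou(pm, rm, config$boundary_band_px)
    out["hausdorff"] <- hausdorff(sdist, config$hausdorff_percentile)
    out["assd"] <- assd(sdist)
  } else {
    diag_px <- sqrt(nrow(pm)^2 + ncol(pm)^2)
    out["nsd"] <- 0
    out["boundary_iou"] <- 0
    out["hausdorff"] <- diag_px
    out["assd"] <- diag_px
  }
  out
}

#' Per-sample metric vector
#'
#' Computes the full battery for one (video, structure) sample: frame-level
#' metrics are averaged over the frames where the structure appears in the
#' reference or the prediction (absent stretches would otherwise dilute the
#' score), and the three temporal metrics are computed once over the whole
#' clip. One such row per sample is the unit of all downstream correlation
#' and ranking analyses.
#'
#' @param pred,ref [label_sequence()] objects sharing `T`, `H`, `W` and
#'   `class_names`.
#' @param structure Structure name (non-background).
#' @param config An [eval_config()].
#' @return A one-row tibble: `video_id`, `structure`, `n_frames_scored`, and
#'   one column per metric.
#' @export
per_sample_metrics <- function(pred, ref, structure, config = eval_config()) {
  if (!identical(dim(pred$frames), dim(ref$frames))) {
    stop("pred and ref differ in shape", call. = FALSE)
  }
  if (!identical(pred$class_names, ref$class_names)) {
    stop("pred and ref differ in class names", call. = FALSE)
  }
  tt <- n_frames(ref)
  acc <- matrix(NA_real_, nrow = tt, ncol = 11L)
  scored <- logical(tt)
  for (t in seq_len(tt)) {
    pm <- structure_mask(pred, structure, t)
    rm <- structure_mask(ref, structure, t)
    if (!any(pm) && !any(rm)) next
    scored[t] <- TRUE
    acc[t, ] <- frame_battery(pm, rm, config)
  }
  if (!any(scored)) {
    stop("structure '", structure, "' absent from both sequences in every frame",
         call. = FALSE)
  }
  frame_means <- colMeans(acc[scored, , drop = FALSE], na.rm = TRUE)
  names(frame_means) <- metric_names[1:11]
  frame_means[is.nan(frame_means)] <- NA_real_
  tc <- if (tt >= 2L) temporal_consistency(pred, structure) else NA_real_
  pcv <- if (tt >= 2L) pixel_count_variation(pred, structure) else NA_real_
  iwv <- if (tt >= 2L) {
    iou_window_variation(pred, ref, structure, config$temporal_window)
  } else NA_real_
  tibble::tibble(
    video_id = ref$video_id, structure = structure,
    n_frames_scored = sum(scored),
    !!!as.list(frame_means),
    temporal_consistency = tc,
    pixel_count_variation = pcv,
    iou_window_variation = iwv
  )
}

#' Evaluate every structure of a video
#'
#' Runs [per_sample_metrics()] for each non-background structure present in
#' the reference or the prediction, yielding the per-(video, structure)
#' rows that downstream correlation analyses consume.
#'
#' @inheritParams per_sample_metrics
#' @param structures Structures to evaluate; defaults to every
#'   non-background class present in either sequence.
#' @return A tibble with one row per structure.
#' @export
evaluate_sequences <- function(pred, ref, config = eval_config(),
                               structures = NULL) {
  if (is.null(structures)) {
    present <- sort(unique(c(as.vector(ref$frames), as.vector(pred$frames))))
    present <- present[present > 0L]
    structures <- ref$class_names[present + 1L]
  }
  purrr::map_dfr(structures, function(s) per_sample_metrics(pred, ref, s, config))
}
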