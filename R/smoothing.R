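#' Temporal smoothing configuration
#'
#' Causal weighted-average window used to suppress flicker in per-frame
#' predictions before they are displayed or evaluated. For the default
#' `K = 10` the weights are `w_k = 1.0 - 0.1 * k` for lags `k = 0..9`, i.e.
#' the current frame carries weight 1.0 and the frame nine steps back 0.1;
#' for other window lengths the same linear taper `w_k = 1 - k / K` is used.
#'
#' @param window Positive window length `K`. Default 10.
#' @param weights Optional custom positive weight vector of length `window`,
#'   largest weight first.
#' @return An object of class `smoothing_config`.
#' @export
smoothing_config <- function(window = 10L, weights = NULL) {
  window <- as.integer(window)
  stopifnot(window >= 1L)
  if (is.null(weights)) {
    weights <- 1 - (seq_len(window) - 1) / window
  }
  if (length(weights) != window || any(weights <= 0) ||
      any(weights > weights[1])) {
    stop("weights must be positive, length `window`, with w_0 the largest",
         call. = FALSE)
  }
  structure(list(window = window, weights = weights), class = "smoothing_config")
}

#' Weighted temporal averaging of predictions
#'
#' Replaces the scores at frame `t` by the weighted average of the last `K`
#' frames, `sum_k w_k * F_(t-k)` over `k = 0..min(K-1, t)`, divided by the
#' sum of the weights actually used, then takes the per-pixel argmax over
#' classes (ties broken toward the lowest class index, i.e. background
#' first). The window is causal: the output at `t` depends only on frames
#' `t-K+1..t`, and is truncated at the start of the clip rather than padded,
#' since zero-padding would bias early frames toward background.
#'
#' Normalizing by the used weight sum does not change the argmax for full
#' windows (the weights sum to a constant there) but keeps the truncated
#' start-up frames on the same score scale.
#'
#' @param pred A [prob_sequence()] of non-negative class scores, or a
#'   [label_sequence()] (one-hot encoded internally via [one_hot()]).
#' @param cfg A [smoothing_config()].
#' @return A [label_sequence()] of the same length.
#' @export
#' @examples
#' fr <- array(0L, c(6, 6, 12)); fr[2:4, 2:4, ] <- 1L
#' s <- smooth_sequence(label_sequence(fr, c("background", "aorta")))
#' identical(s$frames, fr) # constant sequences are fixed points
smooth_sequence <- function(pred, cfg = smoothing_config()) {
  if (inherits(pred, "label_sequence")) pred <- one_hot(pred)
  stopifnot(inherits(pred, "prob_sequence"), inherits(cfg, "smoothing_config"))
  d <- dim(pred$scores)
  h <- d[1]; w <- d[2]; nc <- d[3]; tt <- d[4]
  out <- array(0L, c(h, w, tt))
  for (t in seq_len(tt)) {
    lags <- 0:min(cfg$window - 1L, t - 1L)
    wts <- cfg$weights[lags + 1L]
    avg <- matrix(0, h * w, nc)
    for (i in seq_along(lags)) {
      avg <- avg + wts[i] * matrix(pred$scores[, , , t - lags[i]], h * w, nc)
    }
    avg <- avg / sum(wts)
    out[, , t] <- max.col(avg, ties.method = "first") - 1L
  }
  label_sequence(out, pred$class_names, pred$video_id, pred$fps)
}
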