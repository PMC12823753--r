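#' Pixelwise confusion counts
#'
#' Tallies true/false positives and negatives between a predicted and a
#' reference binary mask on the same pixel grid. All error-specific metrics
#' and the overlap family derive from these four counts, which always sum to
#' the frame size `H * W`.
#'
#' @param pred_mask,ref_mask Logical (or 0/1) matrices of equal dimension.
#' @return A named list with integer fields `tp`, `fp`, `fn`, `tn`.
#' @export
#' @examples
#' ref <- matrix(FALSE, 4, 4); ref[2:3, 2:3] <- TRUE
#' confusion_counts(ref, ref) # tp = 4, tn = 12
confusion_counts <- function(pred_mask, ref_mask) {
  if (!identical(dim(pred_mask), dim(ref_mask))) {
    stop("mask shapes differ", call. = FALSE)
  }
  p <- as.logical(pred_mask)
  r <- as.logical(ref_mask)
  tp <- sum(p & r)
  fp <- sum(p & !r)
  fn <- sum(!p & r)
  list(tp = tp, fp = fp, fn = fn, tn = length(p) - tp - fp - fn)
}

#' Overlap metrics from confusion counts
#'
#' `dice()` is `2 tp / (2 tp + fp + fn)`; `iou()` is `tp / (tp + fp + fn)`.
#' The two are monotonically related (`dice = 2 iou / (1 + iou)`), so they
#' produce identical rank-based correlations. Both return `NA` when both
#' masks are empty (0/0); degenerate-frame handling is the caller's business
#' (see [per_sample_metrics()]).
#'
#' @param c Confusion counts from [confusion_counts()].
#' @return A value in `[0, 1]`, or `NA` for the empty/empty case.
#' @export
dice <- function(c) {
  den <- 2 * c$tp + c$fp + c$fn
  if (den == 0) return(NA_real_)
  2 * c$tp / den
}

#' @rdname dice
#' @export
iou <- function(c) {
  den <- c$tp + c$fp + c$fn
  if (den == 0) return(NA_real_)
  c$tp / den
}

#' F-beta score
#'
#' Weighted harmonic mean of precision and recall,
#' `(1 + b^2) tp / ((1 + b^2) tp + b^2 fn + fp)`; `beta = 1` recovers the
#' Dice score and `beta > 1` weighs recall (missed structure pixels) more
#' heavily than precision.
#'
#' @inheritParams dice
#' @param beta Positive recall weight.
#' @return A value in `[0, 1]`, or `NA` for the empty/empty case.
#' @export
f_beta <- function(c, beta = 2) {
  if (beta <= 0) stop("`beta` must be positive", call. = FALSE)
  b2 <- beta^2
  den <- (1 + b2) * c$tp + b2 * c$fn + c$fp
  if (den == 0) return(NA_real_)
  (1 + b2) * c$tp / den
}

#' Error-specific rates
#'
#' Sensitivity (recall), specificity, false positive rate and false negative
#' rate. A rate whose denominator is zero (e.g. sensitivity when the
#' structure is absent from the reference) is `NA` and skipped during
#' aggregation rather than reported as an arbitrary number.
#'
#' @inheritParams dice
#' @return Named list `sensitivity`, `specificity`, `fpr`, `fnr`.
#' @export
error_rates <- function(c) {
  sens <- if (c$tp + c$fn == 0) NA_real_ else c$tp / (c$tp + c$fn)
  spec <- if (c$tn + c$fp == 0) NA_real_ else c$tn / (c$tn + c$fp)
  list(sensitivity = sens, specificity = spec,
       fpr = 1 - spec, fnr = 1 - sens)
}

#' Boundary pixels of a binary mask
#'
#' A mask pixel is a boundary pixel when at least one of its 4-neighbors is
#' outside the mask; the frame edge counts as outside. 4-connectivity and
#' Euclidean pixel distances are fixed conventions of the whole distance
#' family so that brute-force checks are exact.
#'
#' @param mask Logical matrix.
#' @return Logical matrix marking boundary pixels.
#' @export
extract_boundary <- function(mask) {
  m <- mask
  storage.mode(m) <- "logical"
  if (!any(m)) return(m)
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- m
  inner <- pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
    pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  m & !inner
}

# Minimum Euclidean distance from each point in `pts` to the set `set`;
# both are n x 2 matrices of (row, col). Double precision throughout.
min_dist_to_set <- function(pts, set) {
  if (nrow(pts) == 0L) return(numeric(0))
  d2 <- outer(pts[, 1], set[, 1], "-")^2 + outer(pts[, 2], set[, 2], "-")^2
  unname(sqrt(apply(d2, 1, min)))
}

mask_coords <- function(mask) {
  which(mask, arr.ind = TRUE)
}

#' Directed surface distances between two masks
#'
#' For every boundary pixel of one mask, the minimum Euclidean distance to
#' the other mask's boundary set, in both directions. These sets feed the
#' Hausdorff distance, the average symmetric surface distance, and the
#' normalized surface Dice.
#'
#' @param pred_mask,ref_mask Non-empty logical matrices of equal dimension.
#' @return A list of class `surface_distances` with numeric vectors
#'   `d_pred_to_ref` and `d_ref_to_pred`.
#' @export
surface_distances <- function(pred_mask, ref_mask) {
  if (!identical(dim(pred_mask), dim(ref_mask))) {
    stop("mask shapes differ", call. = FALSE)
  }
  bp <- mask_coords(extract_boundary(pred_mask))
  br <- mask_coords(extract_boundary(ref_mask))
  if (nrow(bp) == 0L || nrow(br) == 0L) {
    stop("surface distances need two non-empty masks", call. = FALSE)
  }
  structure(
    list(d_pred_to_ref = min_dist_to_set(bp, br),
         d_ref_to_pred = min_dist_to_set(br, bp)),
    class = "surface_distances"
  )
}

#' Hausdorff distance (optionally percentile-robust)
#'
#' The maximum over both directions of the given percentile of directed
#' boundary distances; `percentile = 100` gives the classical maximum
#' deviation, 95 the common robust variant.
#'
#' @param s A [surface_distances()] set.
#' @param percentile Percentile in `(0, 100]`.
#' @return Non-negative distance in pixels.
#' @export
hausdorff <- function(s, percentile = 100) {
  stopifnot(percentile > 0, percentile <= 100)
  if (length(s$d_pred_to_ref) == 0L || length(s$d_ref_to_pred) == 0L) {
    stop("empty distance list", call. = FALSE)
  }
  if (percentile == 100) {
    max(max(s$d_pred_to_ref), max(s$d_ref_to_pred))
  } else {
    max(stats::quantile(s$d_pred_to_ref, percentile / 100, names = FALSE),
        stats::quantile(s$d_ref_to_pred, percentile / 100, names = FALSE))
  }
}

#' Average symmetric surface distance
#'
#' Mean boundary deviation pooled over both directions:
#' `(sum d_pred_to_ref + sum d_ref_to_pred) / (n_pred + n_ref)`.
#'
#' @inheritParams hausdorff
#' @return Non-negative distance in pixels; never exceeds [hausdorff()].
#' @export
assd <- function(s) {
  n <- length(s$d_pred_to_ref) + length(s$d_ref_to_pred)
  if (n == 0L) stop("empty distance list", call. = FALSE)
  (sum(s$d_pred_to_ref) + sum(s$d_ref_to_pred)) / n
}

#' Normalized surface Dice
#'
#' Fraction of boundary points (both directions pooled) lying within
#' tolerance `tau` of the other mask's boundary. 1 means every boundary
#' point is within clinically acceptable deviation; monotone non-decreasing
#' in `tau`.
#'
#' @inheritParams hausdorff
#' @param tau Positive tolerance in pixels.
#' @return Value in `[0, 1]`.
#' @export
nsd <- function(s, tau) {
  if (tau <= 0) stop("`tau` must be positive", call. = FALSE)
  n <- length(s$d_pred_to_ref) + length(s$d_ref_to_pred)
  if (n == 0L) stop("empty distance list", call. = FALSE)
  (sum(s$d_pred_to_ref <= tau) + sum(s$d_ref_to_pred <= tau)) / n
}

# Pixels of `mask` within Euclidean distance d of the mask's own boundary.
boundary_band <- function(mask, d) {
  b <- extract_boundary(mask)
  if (!any(b)) return(b)
  pts <- mask_coords(mask)
  keep <- min_dist_to_set(pts, mask_coords(b)) <= d
  band <- mask
  band[] <- FALSE
  band[pts[keep, , drop = FALSE]] <- TRUE
  band
}

#' Boundary IoU
#'
#' IoU restricted to a band of width `d` around each mask's own boundary:
#' interior agreement is discounted so the score isolates boundary quality,
#' which matters most where overlays meet dissection planes.
#'
#' @param pred_mask,ref_mask Non-empty logical matrices of equal dimension.
#' @param d Band width in pixels (integer `>= 1`).
#' @return Value in `[0, 1]`.
#' @export
boundary_iou <- function(pred_mask, ref_mask, d) {
  if (d < 1) stop("`d` must be a positive integer", call. = FALSE)
  if (!any(pred_mask) || !any(ref_mask)) {
    stop("boundary IoU needs two non-empty masks", call. = FALSE)
  }
  bp <- pred_mask & boundary_band(pred_mask, d)
  br <- ref_mask & boundary_band(ref_mask, d)
  iou(confusion_counts(bp, br))
}
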