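#' Label-map video sequence
#'
#' A `label_sequence` holds `T` ordered frames of integer class labels on a
#' common `H x W` pixel grid. Label `0` is always background; label `i`
#' refers to `class_names[i + 1]`. This is the unit on which every metric in
#' the battery is computed.
#'
#' @param frames Integer array of dimension `c(H, W, T)` (a single `H x W`
#'   matrix is promoted to `T = 1`). Values must lie in
#'   `0:(length(class_names) - 1)`.
#' @param class_names Character vector of structure names; the first entry is
#'   the background class.
#' @param video_id Identifier of the clip.
#' @param fps Frames per second (informational only).
#'
#' @return An object of class `label_sequence` with fields `frames`,
#'   `class_names`, `video_id` and `fps`.
#' @seealso [prob_sequence()], [read_label_sequence()], [smooth_sequence()]
#' @export
#' @examples
#' fr <- array(0L, c(4, 4, 2))
#' fr[2:3, 2:3, ] <- 1L
#' label_sequence(fr, c("background", "aorta"), video_id = "demo")
label_sequence <- function(frames, class_names, video_id = "video", fps = 25) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("`frames` must be an H x W x T array", call. = FALSE)
  }
  if (dim(frames)[3] < 1L) stop("sequence needs at least one frame", call. = FALSE)
  if (!is.character(class_names) || length(class_names) < 1L) {
    stop("`class_names` must be a non-empty character vector", call. = FALSE)
  }
  storage.mode(frames) <- "integer"
  if (anyNA(frames) || min(frames) < 0L || max(frames) >= length(class_names)) {
    stop("labels must lie in 0..", length(class_names) - 1L, call. = FALSE)
  }
  structure(
    list(frames = frames, class_names = class_names,
         video_id = as.character(video_id), fps = fps),
    class = "label_sequence"
  )
}

#' @export
print.label_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<label_sequence '%s': %d frames of %dx%d, %d classes>\n",
              x$video_id, d[3], d[1], d[2], length(x$class_names)))
  cat("classes:", paste(x$class_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.label_sequence <- function(x) dim(x$frames)

n_frames <- function(x) dim(x$frames)[3]

#' Per-class score video sequence
#'
#' A `prob_sequence` carries non-negative per-pixel class scores (softmax
#' probabilities, logits shifted to be non-negative, or one-hot labels) for
#' each frame. It is the input representation for [smooth_sequence()]: the
#' weighted temporal average is taken on scores, and labels are recovered by
#' per-pixel argmax.
#'
#' @param scores Numeric array of dimension `c(H, W, C, T)` where
#'   `C = length(class_names)` (background channel included). All values must
#'   be finite and `>= 0`.
#' @inheritParams label_sequence
#'
#' @return An object of class `prob_sequence`.
#' @export
prob_sequence <- function(scores, class_names, video_id = "video", fps = 25) {
  if (!is.array(scores) || length(dim(scores)) != 4L) {
    stop("`scores` must be an H x W x C x T array", call. = FALSE)
  }
  if (dim(scores)[3] != length(class_names)) {
    stop("third dimension must match length(class_names)", call. = FALSE)
  }
  if (!all(is.finite(scores)) || min(scores) < 0) {
    stop("scores must be finite and non-negative", call. = FALSE)
  }
  structure(
    list(scores = scores, class_names = class_names,
         video_id = as.character(video_id), fps = fps),
    class = "prob_sequence"
  )
}

#' @export
print.prob_sequence <- function(x, ...) {
  d <- dim(x$scores)
  cat(sprintf("<prob_sequence '%s': %d frames of %dx%d, %d classes>\n",
              x$video_id, d[4], d[1], d[2], d[3]))
  invisible(x)
}

#' One-hot encode a label sequence
#'
#' Lifts hard labels into the score representation accepted by
#' [smooth_sequence()]: channel `c` of frame `t` is 1 where the label equals
#' `c - 1` and 0 elsewhere.
#'
#' @param seq A [label_sequence()].
#' @return A [prob_sequence()] with one channel per class.
#' @export
one_hot <- function(seq) {
  stopifnot(inherits(seq, "label_sequence"))
  d <- dim(seq$frames)
  nc <- length(seq$class_names)
  scores <- array(0, c(d[1], d[2], nc, d[3]))
  for (k in seq_len(nc)) {
    scores[, , k, ] <- as.numeric(seq$frames == (k - 1L))
  }
  prob_sequence(scores, seq$class_names, seq$video_id, seq$fps)
}

# Binary mask of one structure in one frame.
structure_mask <- function(seq, structure, t) {
  id <- match(structure, seq$class_names) - 1L
  if (is.na(id)) stop("unknown structure: ", structure, call. = FALSE)
  if (id == 0L) stop("background is not a rateable structure", call. = FALSE)
  seq$frames[, , t] == id
}
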