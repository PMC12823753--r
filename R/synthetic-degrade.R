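#' Degradation configuration for one structure
#'
#' Parameterizes the error modes surgeons report in practice: boundary
#' overreach or shrinkage (dilation/erosion), systematic spatial offset
#' (translation), unstable boundaries (per-frame jitter), flicker (whole
#' predictions dropping out for single frames), hallucinated components of
#' the class appearing elsewhere, and systematic class confusion
#' (relabeling). The all-zero default is the identity: the degraded
#' sequence then equals the reference exactly.
#'
#' @param dilate_erode_px Signed integer; `+k` dilates (over-segmentation),
#'   `-k` erodes, by a disc of radius `k` pixels.
#' @param translate_px Integer `(dy, dx)` shift applied to the structure.
#' @param flicker_dropout_prob Per-frame probability in `[0, 1]` that the
#'   structure's prediction is emptied for that frame.
#' @param hallucination_prob Per-frame probability in `[0, 1]` that a
#'   spurious disk of this class is inserted away from the structure.
#' @param hallucination_radius_px Radius of the hallucinated disk (the study
#'   builder sets this to half the structure's mean radius).
#' @param relabel_as Optional class name: the structure's prediction is
#'   painted with that class instead of its own (class confusion).
#' @param boundary_noise_px Non-negative jitter amplitude: each frame the
#'   boundary is dilated or eroded by an independent uniform amount in
#'   `[-a, a]` pixels.
#' @return An object of class `degradation_config`.
#' @export
degradation_config <- function(dilate_erode_px = 0L, translate_px = c(0L, 0L),
                               flicker_dropout_prob = 0,
                               hallucination_prob = 0,
                               hallucination_radius_px = 4,
                               relabel_as = NULL,
                               boundary_noise_px = 0L) {
  stopifnot(flicker_dropout_prob >= 0, flicker_dropout_prob <= 1,
            hallucination_prob >= 0, hallucination_prob <= 1,
            hallucination_radius_px > 0,
            boundary_noise_px >= 0, length(translate_px) == 2L)
  structure(
    list(dilate_erode_px = as.integer(dilate_erode_px),
         translate_px = as.integer(translate_px),
         flicker_dropout_prob = flicker_dropout_prob,
         hallucination_prob = hallucination_prob,
         hallucination_radius_px = hallucination_radius_px,
         relabel_as = relabel_as,
         boundary_noise_px = as.integer(boundary_noise_px)),
    class = "degradation_config"
  )
}

# Morphological dilation (k > 0) / erosion (k < 0) by a disc of radius |k|.
morph_mask <- function(m, k) {
  if (k == 0L || !any(m)) return(m)
  brush <- EBImage::makeBrush(2L * abs(k) + 1L, shape = "disc")
  num <- matrix(as.numeric(m), nrow(m), ncol(m))
  res <- if (k > 0L) EBImage::dilate(num, brush) else EBImage::erode(num, brush)
  res > 0.5
}

shift_mask <- function(m, dy, dx) {
  if ((dy == 0L && dx == 0L) || !any(m)) return(m)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  src_r <- seq_len(h) - dy
  src_c <- seq_len(w) - dx
  ok_r <- src_r >= 1L & src_r <= h
  ok_c <- src_c >= 1L & src_c <= w
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# Disk of the structure's class placed away from its reference region.
place_hallucination <- function(ref_mask, r) {
  h <- nrow(ref_mask); w <- ncol(ref_mask)
  for (try in seq_len(50L)) {
    cy <- stats::runif(1, r + 1, h - r)
    cx <- stats::runif(1, r + 1, w - r)
    d <- disk_mask(h, w, cy, cx, r)
    if (!any(d & ref_mask)) return(d)
  }
  matrix(FALSE, h, w)
}

#' Apply controlled degradations to a reference sequence
#'
#' Builds a synthetic "prediction" from a reference by corrupting each
#' configured structure frame by frame, in this order: dilation/erosion,
#' translation, boundary jitter, flicker dropout, hallucination insertion,
#' relabeling. Unconfigured structures pass through unchanged; vacated
#' pixels become background; structures are re-painted in class order so
#' later classes overwrite earlier ones exactly as in the reference
#' generator. Deterministic given `seed`.
#'
#' @param ref A [label_sequence()].
#' @param per_structure Named list: structure name -> [degradation_config()].
#' @param seed Integer seed for the stochastic error modes.
#' @return A [label_sequence()] with the same shape and class names.
#' @export
degrade_sequence <- function(ref, per_structure = list(), seed = 1L) {
  stopifnot(inherits(ref, "label_sequence"))
  unknown <- setdiff(names(per_structure), ref$class_names)
  if (length(unknown) > 0) {
    stop("unknown structure name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  tt <- n_frames(ref)
  out <- array(0L, dim(ref$frames))
  for (ci in seq_along(ref$class_names)[-1]) {
    name <- ref$class_names[ci]
    id <- ci - 1L
    cfg <- per_structure[[name]]
    if (is.null(cfg)) {
      sel <- ref$frames == id
      out[sel] <- id
      next
    }
    paint_id <- if (is.null(cfg$relabel_as)) id else {
      pid <- match(cfg$relabel_as, ref$class_names) - 1L
      if (is.na(pid)) stop("unknown relabel target: ", cfg$relabel_as, call. = FALSE)
      pid
    }
    withr::local_seed(derive_seed(seed, paste0("degrade_", name)))
    for (t in seq_len(tt)) {
      ref_m <- ref$frames[, , t] == id
      m <- ref_m
      if (any(m)) {
        m <- morph_mask(m, cfg$dilate_erode_px)
        m <- shift_mask(m, cfg$translate_px[1], cfg$translate_px[2])
        if (cfg$boundary_noise_px > 0L) {
          jit <- sample.int(2L * cfg$boundary_noise_px + 1L, 1L) -
            cfg$boundary_noise_px - 1L
          m <- morph_mask(m, jit)
        }
      }
      if (cfg$flicker_dropout_prob > 0 &&
          stats::runif(1) < cfg$flicker_dropout_prob) {
        m[] <- FALSE
      }
      if (cfg$hallucination_prob > 0 &&
          stats::runif(1) < cfg$hallucination_prob) {
        m <- m | place_hallucination(ref_m, cfg$hallucination_radius_px)
      }
      if (any(m)) {
        fr <- out[, , t]
        fr[m] <- paint_id
        out[, , t] <- fr
      }
    }
  }
  label_sequence(out, ref$class_names, ref$video_id, ref$fps)
}
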