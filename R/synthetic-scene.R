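#' Synthetic scene configuration
#'
#' Describes the reference material the generator emulates: short clips in
#' which each anatomical structure is a connected ellipse-like blob drifting
#' on a seeded random walk. The emulation targets geometry and motion only —
#' no texture or photorealism — because every downstream quantity (masks,
#' metrics, ratings) depends only on label geometry.
#'
#' @param n_videos Number of clips.
#' @param frames_per_video Frames per clip.
#' @param height,width Frame size in pixels.
#' @param structures Data frame with columns `name`, `mean_radius_px`,
#'   `motion_step_px`: one row per structure drawn in every clip of this
#'   scene (later rows overwrite earlier ones where blobs overlap).
#' @param rng_seed Integer seed; generation is a pure function of
#'   `(rng_seed, video_index)`.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(n_videos = 1L, frames_per_video = 30L,
                         height = 64L, width = 64L,
                         structures, rng_seed = 1L) {
  structures <- tibble::as_tibble(structures)
  stopifnot(nrow(structures) >= 1L,
            all(c("name", "mean_radius_px", "motion_step_px") %in% names(structures)),
            all(structures$mean_radius_px > 0),
            all(structures$motion_step_px >= 0),
            frames_per_video >= 1, height >= 4, width >= 4)
  if (anyDuplicated(structures$name)) {
    stop("duplicate structure names", call. = FALSE)
  }
  structure(
    list(n_videos = as.integer(n_videos),
         frames_per_video = as.integer(frames_per_video),
         height = as.integer(height), width = as.integer(width),
         structures = structures, rng_seed = as.integer(rng_seed)),
    class = "scene_config"
  )
}

# Rasterize a rotated ellipse with semi-axes (a, b) centred at (cy, cx).
ellipse_mask <- function(h, w, cy, cx, a, b, theta) {
  rows <- matrix(seq_len(h), h, w) - cy
  cols <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  u <- rows * cos(theta) + cols * sin(theta)
  v <- -rows * sin(theta) + cols * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

disk_mask <- function(h, w, cy, cx, r) ellipse_mask(h, w, cy, cx, r, r, 0)

#' Generate a synthetic reference sequence
#'
#' Each structure is an ellipse with the configured mean radius (semi-axes
#' `r * f` and `r / f` for a per-clip shape factor `f`, so the area stays
#' close to `pi r^2`) whose centre performs a random walk with per-frame
#' Euclidean displacement at most `motion_step_px`, clamped so the blob
#' always fits in the frame. Structures listed later overwrite earlier ones
#' where they overlap, preserving the one-label-per-pixel invariant.
#'
#' @param scene A [scene_config()].
#' @param video_index Clip index (1-based); part of the seed, so every clip
#'   of a scene is distinct yet reproducible.
#' @param class_names Optional full class vocabulary (first = background).
#'   Defaults to `c("background", scene$structures$name)`; supplying a
#'   larger vocabulary keeps label ids comparable across clips that contain
#'   different structure subsets.
#' @return A [label_sequence()].
#' @export
generate_reference_sequence <- function(scene, video_index = 1L,
                                        class_names = NULL) {
  stopifnot(inherits(scene, "scene_config"))
  if (is.null(class_names)) {
    class_names <- c("background", scene$structures$name)
  }
  if (!all(scene$structures$name %in% class_names[-1])) {
    stop("scene structures missing from class_names", call. = FALSE)
  }
  h <- scene$height; w <- scene$width; tt <- scene$frames_per_video
  withr::local_seed(derive_seed(scene$rng_seed, paste0("scene_", video_index)))
  frames <- array(0L, c(h, w, tt))
  placed_masks <- list()
  for (i in seq_len(nrow(scene$structures))) {
    st <- scene$structures[i, ]
    f <- stats::runif(1, 0.8, 1.25)
    a <- st$mean_radius_px * f
    b <- st$mean_radius_px / f
    theta <- stats::runif(1, 0, pi)
    margin <- ceiling(max(a, b)) + 1
    if (2 * margin >= min(h, w)) {
      stop("structure '", st$name, "' cannot fit in a ", h, "x", w, " frame",
           call. = FALSE)
    }
    # Resample the starting position until the blob barely overlaps what is
    # already placed: occlusion between structures stays partial, so no
    # structure is buried by a later-painted one.
    placed <- frames[, , 1] > 0L
    cy <- cx <- NA_real_
    for (try in seq_len(200L)) {
      y <- stats::runif(1, margin + 1, h - margin)
      x <- stats::runif(1, margin + 1, w - margin)
      cand <- ellipse_mask(h, w, y, x, a, b, theta)
      buries <- any(vapply(placed_masks, function(pm) {
        sum(cand & pm) > 0.5 * sum(pm)
      }, logical(1)))
      if (sum(cand & placed) <= 0.2 * sum(cand) && !buries) {
        cy <- y; cx <- x
        break
      }
    }
    if (is.na(cy)) { cy <- y; cx <- x }
    placed_masks[[st$name]] <- ellipse_mask(h, w, cy, cx, a, b, theta)
    id <- match(st$name, class_names) - 1L
    for (t in seq_len(tt)) {
      if (t > 1L && st$motion_step_px > 0) {
        step <- stats::runif(1, 0, st$motion_step_px)
        ang <- stats::runif(1, 0, 2 * pi)
        cy <- min(max(cy + step * sin(ang), margin + 1), h - margin)
        cx <- min(max(cx + step * cos(ang), margin + 1), w - margin)
      }
      m <- ellipse_mask(h, w, cy, cx, a, b, theta)
      fr <- frames[, , t]
      fr[m] <- id
      frames[, , t] <- fr
    }
  }
  label_sequence(frames, class_names,
                 video_id = sprintf("video_%02d", video_index))
}
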