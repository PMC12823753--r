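# Shared fixtures built in code.

two_class_names <- c("background", "aorta")

# Sequence of a static square structure.
static_square_sequence <- function(tt = 3, h = 8, w = 8, id = 1L,
                                   class_names = two_class_names) {
  fr <- array(0L, c(h, w, tt))
  fr[3:5, 3:5, ] <- id
  label_sequence(fr, class_names)
}

random_label_sequence <- function(tt = 5, h = 6, w = 6, n_classes = 3,
                                  seed = 1) {
  withr::with_seed(seed, {
    fr <- array(sample(0:(n_classes - 1), h * w * tt, replace = TRUE),
                c(h, w, tt))
  })
  label_sequence(fr, c("background", paste0("s", seq_len(n_classes - 1))))
}

# One-structure scene used by smoothing/degradation properties.
one_disk_scene <- function(seed = 1, tt = 20, h = 48, w = 48, radius = 8,
                           step = 0) {
  scene_config(
    frames_per_video = tt, height = h, width = w,
    structures = data.frame(name = "aorta", mean_radius_px = radius,
                            motion_step_px = step),
    rng_seed = seed
  )
}

# The default study is expensive enough to build once per test run.
cached_default_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_study(default_study_config(seed = 1))
    cache
  }
})

# Synthetic per-sample table for observer/stability tests that do not need
# real segmentations: metrics as monotone/noisy functions of a latent.
toy_metric_table <- function(n = 12, seed = 1) {
  withr::with_seed(seed, {
    q <- runif(n, 0.1, 0.95)
    tibble::tibble(
      video_id = sprintf("video_%02d", seq_len(n)),
      structure = "aorta",
      dice = q,
      iou = q / (2 - q),               # exact monotone pairing
      sensitivity = pmin(1, q + rnorm(n, 0, 0.05)),
      fnr = NA_real_,
      assd = 20 * (1 - q) + rnorm(n, 0, 1)
    ) |>
      dplyr::mutate(sensitivity = pmin(1, pmax(0, sensitivity)),
                    fnr = 1 - sensitivity)
  })
}

one_rater_records <- function(samples, ratings) {
  tibble::tibble(
    participant_id = "expert_01", cases_performed = 150L, cases_assisted = 10L,
    video_id = samples$video_id, structure = samples$structure,
    accuracy_rating = as.integer(ratings),
    identification_rating = as.integer(ratings)
  )
}
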