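test_that("reference generation is deterministic and static when frozen", {
  scene <- one_disk_scene(seed = 11, tt = 8, step = 0)
  a <- generate_reference_sequence(scene)
  b <- generate_reference_sequence(scene)
  expect_identical(a$frames, b$frames)
  # motion_step_px = 0: identical mask in every frame
  expect_true(all(apply(a$frames, 3, identical, a$frames[, , 1])))

  scene$rng_seed <- 12
  expect_false(identical(generate_reference_sequence(scene)$frames, a$frames))

  big <- one_disk_scene(tt = 2, h = 16, w = 16, radius = 20)
  expect_error(generate_reference_sequence(big), "cannot fit")
})

test_that("generated blob areas follow the configured radius", {
  scene <- one_disk_scene(seed = 2, tt = 100, h = 48, w = 48, radius = 10,
                          step = 2)
  s <- generate_reference_sequence(scene)
  areas <- apply(s$frames == 1L, 3, sum)
  expect_lt(abs(mean(areas) - pi * 100) / (pi * 100), 0.25)
})

test_that("zero degradation is the identity", {
  scene <- scene_config(
    frames_per_video = 6, height = 48, width = 48,
    structures = data.frame(name = c("aorta", "nerves"),
                            mean_radius_px = c(8, 4),
                            motion_step_px = c(1, 2)),
    rng_seed = 3
  )
  ref <- generate_reference_sequence(scene)
  pred <- degrade_sequence(ref, list(aorta = degradation_config(),
                                     nerves = degradation_config()), seed = 9)
  expect_identical(pred$frames, ref$frames)
  expect_error(degrade_sequence(ref, list(spleen = degradation_config())),
               "unknown structure")
})

test_that("dilation gives perfect sensitivity but imperfect precision", {
  ref <- static_square_sequence(1, h = 16, w = 16)
  ref$frames[5:9, 5:9, 1] <- 1L
  pred <- degrade_sequence(
    ref, list(aorta = degradation_config(dilate_erode_px = 2L)), seed = 1)
  pm <- pred$frames[, , 1] == 1L
  rm <- ref$frames[, , 1] == 1L
  cc <- brute_confusion(pm, rm)
  expect_equal(cc$fn, 0L)                       # sensitivity 1
  expect_gt(cc$fp, 0L)                          # precision < 1
  expect_true(all(pm[rm]))                      # dilation is a superset
})

test_that("degradation severity decreases dice monotonically", {
  scene <- one_disk_scene(seed = 5, tt = 4, h = 48, w = 48, radius = 9)
  ref <- generate_reference_sequence(scene)
  dices <- sapply(c(0L, 1L, 2L, 3L), function(k) {
    pred <- degrade_sequence(
      ref, list(aorta = degradation_config(dilate_erode_px = k)), seed = 1)
    per_sample_metrics(pred, ref, "aorta")$dice
  })
  expect_true(all(diff(dices) <= 1e-12))
})

test_that("hallucinations appear away from the true structure", {
  scene <- one_disk_scene(seed = 8, tt = 10, h = 48, w = 48, radius = 7)
  ref <- generate_reference_sequence(scene)
  pred <- degrade_sequence(
    ref, list(aorta = degradation_config(hallucination_prob = 1,
                                         hallucination_radius_px = 3)),
    seed = 2)
  extra <- (pred$frames == 1L) & !(ref$frames == 1L)
  expect_gt(sum(extra), 0)
  # the inserted component never overlaps the reference mask
  expect_true(all(pred$frames[ref$frames == 1L] == 1L))
})

test_that("relabeling paints the structure as the confused class", {
  scene <- scene_config(
    frames_per_video = 3, height = 48, width = 48,
    structures = data.frame(name = c("airways", "pericardium"),
                            mean_radius_px = c(7, 9),
                            motion_step_px = c(0, 0)),
    rng_seed = 4
  )
  ref <- generate_reference_sequence(scene)
  pred <- degrade_sequence(
    ref, list(airways = degradation_config(relabel_as = "pericardium")),
    seed = 1)
  expect_false(any(pred$frames == 1L))
  # airway pixels now carry the pericardium label
  expect_true(all(pred$frames[ref$frames == 1L] == 2L))
})

test_that("the rater model is exact in the noiseless limit", {
  cfg <- eval_config()
  g <- list(rater_group_config("expert", 1, leniency = 0, sensitivity = 1,
                               noise_sd = 0))
  q <- tibble::tibble(video_id = "v", structure = c("a", "b"),
                      quality = c(1, 0))
  r <- simulate_ratings(q, g, cfg, seed = 1)
  expect_identical(r$accuracy_rating, c(5L, 1L))
  expect_error(simulate_ratings(dplyr::mutate(q, quality = c(2, 0)), g, cfg),
               "\\[0, 1\\]")
})

test_that("rater profiles classify into their declared group", {
  r <- simulate_ratings(
    tibble::tibble(video_id = "v", structure = "a", quality = 0.5),
    default_rater_groups(), seed = 42)
  prof <- dplyr::distinct(r, participant_id, cases_performed, cases_assisted)
  declared <- sub("_[0-9]+$", "", prof$participant_id)
  got <- as.character(assign_experience_group(prof$cases_performed,
                                              prof$cases_assisted))
  expect_identical(got, declared)
  expect_equal(sum(declared == "expert"), 7)
  expect_equal(sum(declared == "intermediate"), 11)
  expect_equal(sum(declared == "novice"), 8)

  expect_error(rater_group_config("novice", 3,
                                  cases_performed_range = c(0, 50)),
               "inconsistent")
})

test_that("novices rate leniently, experts track quality (50 seeds)", {
  withr::with_seed(1, {
    q <- tibble::tibble(video_id = sprintf("v%02d", 1:46), structure = "a",
                        quality = runif(46, 0.2, 0.95))
  })
  lenient <- 0; tracking <- 0
  n_seeds <- 50
  for (s in seq_len(n_seeds)) {
    r <- simulate_ratings(q, default_rater_groups(), seed = s)
    grp <- assign_experience_group(r$cases_performed, r$cases_assisted)
    mean_nov <- mean(r$accuracy_rating[grp == "novice"])
    mean_exp <- mean(r$accuracy_rating[grp == "expert"])
    if (mean_nov > mean_exp) lenient <- lenient + 1
    rho_by <- function(g) {
      sub <- r[grp == g, ]
      agg <- tapply(sub$accuracy_rating, sub$video_id, mean)
      spearman_abs(as.numeric(agg[q$video_id]), q$quality)
    }
    if (rho_by("expert") > rho_by("novice")) tracking <- tracking + 1
  }
  expect_gte(lenient, 48)
  expect_gte(tracking, 40)
})
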