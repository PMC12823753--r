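test_that("temporal consistency: static = 1, alternating with empty = 0", {
  expect_equal(temporal_consistency(static_square_sequence(5), "aorta"), 1)

  fr <- array(0L, c(8, 8, 6))
  fr[3:5, 3:5, c(1, 3, 5)] <- 1L   # disk present only on odd frames
  alt <- label_sequence(fr, two_class_names)
  expect_equal(temporal_consistency(alt, "aorta"), 0)

  never <- label_sequence(array(0L, c(4, 4, 3)), two_class_names)
  expect_true(is.na(temporal_consistency(never, "aorta")))
  expect_error(temporal_consistency(static_square_sequence(1), "aorta"),
               "at least 2")
})

test_that("temporal consistency equals brute-force pairwise IoU", {
  s <- random_label_sequence(tt = 8, h = 6, w = 6, n_classes = 3, seed = 5)
  vals <- c()
  for (t in 2:8) {
    a <- s$frames[, , t] == 1L
    b <- s$frames[, , t - 1L] == 1L
    if (any(a) || any(b)) {
      cc <- brute_confusion(a, b)
      vals <- c(vals, cc$tp / (cc$tp + cc$fp + cc$fn))
    }
  }
  expect_equal(temporal_consistency(s, "s1"), mean(vals))
})

test_that("pixel count variation matches direct arithmetic", {
  # counts 100, 0, 100, 0
  fr <- array(0L, c(12, 12, 4))
  fr[1:10, 1:10, c(1, 3)] <- 1L
  s <- label_sequence(fr, two_class_names)
  expect_equal(pixel_count_variation(s, "aorta"), 2)

  expect_equal(pixel_count_variation(static_square_sequence(4), "aorta"), 0)

  # invariant under frame-order reversal
  r <- random_label_sequence(tt = 7, seed = 9)
  rev <- label_sequence(r$frames[, , 7:1], r$class_names)
  expect_equal(pixel_count_variation(r, "s1"), pixel_count_variation(rev, "s1"))
})

test_that("IoU window variation: constants, alternation, brute force", {
  s <- static_square_sequence(12)
  expect_equal(iou_window_variation(s, s, "aorta", 10), 0)

  # per-frame IoU alternating 1, 0: pred equals ref on odd frames, disjoint
  # on even frames -> each balanced 10-window has population sd 0.5
  fr_ref <- array(0L, c(10, 10, 20)); fr_ref[2:4, 2:4, ] <- 1L
  fr_pred <- fr_ref
  fr_pred[, , seq(2, 20, by = 2)] <- 0L
  fr_pred[7:9, 7:9, seq(2, 20, by = 2)] <- 1L
  ref <- label_sequence(fr_ref, two_class_names)
  pred <- label_sequence(fr_pred, two_class_names)
  expect_equal(iou_window_variation(pred, ref, "aorta", 10), 0.5)

  # random sequences against a brute-force windowed sd
  p <- random_label_sequence(tt = 15, seed = 2)
  r <- random_label_sequence(tt = 15, seed = 3)
  ious <- sapply(1:15, function(t) {
    a <- p$frames[, , t] == 1L; b <- r$frames[, , t] == 1L
    if (!any(a) && !any(b)) return(NA_real_)
    cc <- brute_confusion(a, b)
    cc$tp / (cc$tp + cc$fp + cc$fn)
  })
  ious <- ious[!is.na(ious)]
  w <- 10
  sds <- sapply(seq_len(length(ious) - w + 1), function(s0) {
    win <- ious[s0:(s0 + w - 1)]
    sqrt(mean((win - mean(win))^2))
  })
  expect_equal(iou_window_variation(p, r, "s1", w), mean(sds))
})

test_that("per-sample metrics: perfect prediction scores perfectly", {
  s <- static_square_sequence(12)
  row <- per_sample_metrics(s, s, "aorta")
  expect_equal(row$dice, 1)
  expect_equal(row$iou, 1)
  expect_equal(row$nsd, 1)
  expect_equal(row$boundary_iou, 1)
  expect_equal(row$sensitivity, 1)
  expect_equal(row$specificity, 1)
  expect_equal(row$hausdorff, 0)
  expect_equal(row$assd, 0)
  expect_equal(row$temporal_consistency, 1)
  expect_equal(row$pixel_count_variation, 0)
  expect_equal(row$iou_window_variation, 0)
})

test_that("total dropout forces dice 0 and diagonal distance penalties", {
  ref <- static_square_sequence(6, h = 8, w = 8)
  pred <- degrade_sequence(
    ref, list(aorta = degradation_config(flicker_dropout_prob = 1)), seed = 1)
  expect_true(all(pred$frames == 0L))
  row <- per_sample_metrics(pred, ref, "aorta")
  expect_equal(row$dice, 0)
  expect_equal(row$assd, sqrt(8^2 + 8^2))
  expect_equal(row$hausdorff, sqrt(8^2 + 8^2))
  expect_equal(row$nsd, 0)
  expect_equal(row$sensitivity, 0)
})

test_that("a 3-frame toy sequence equals the hand-computed frame average", {
  cfg <- eval_config()
  h <- 6; w <- 6
  ref_fr <- array(0L, c(h, w, 3)); pred_fr <- array(0L, c(h, w, 3))
  # frame 1: identical squares; frame 2: pred shifted by 1 col;
  # frame 3: structure only in ref
  ref_fr[2:3, 2:3, 1] <- 1L; pred_fr[2:3, 2:3, 1] <- 1L
  ref_fr[2:3, 2:3, 2] <- 1L; pred_fr[2:3, 3:4, 2] <- 1L
  ref_fr[2:3, 2:3, 3] <- 1L
  ref <- label_sequence(ref_fr, two_class_names)
  pred <- label_sequence(pred_fr, two_class_names)
  row <- per_sample_metrics(pred, ref, "aorta", cfg)

  dice_frames <- c(1, {cc <- brute_confusion(pred_fr[, , 2] == 1, ref_fr[, , 2] == 1)
                       2 * cc$tp / (2 * cc$tp + cc$fp + cc$fn)}, 0)
  expect_equal(row$dice, mean(dice_frames))
  sens_frames <- c(1, 0.5, 0)
  expect_equal(row$sensitivity, mean(sens_frames))
  # distances: 0 on frame 1, brute force on frame 2, diagonal on frame 3
  d2 <- c(brute_directed_distances(pred_fr[, , 2] == 1, ref_fr[, , 2] == 1),
          brute_directed_distances(ref_fr[, , 2] == 1, pred_fr[, , 2] == 1))
  expect_equal(row$assd, mean(c(0, mean(d2), sqrt(72))))
  expect_equal(row$n_frames_scored, 3L)
})

test_that("per-sample metrics error when the structure never appears", {
  bg <- label_sequence(array(0L, c(4, 4, 2)), two_class_names)
  expect_error(per_sample_metrics(bg, bg, "aorta"), "absent from both")
})

test_that("flicker degrades temporal metrics monotonically in expectation", {
  scene <- one_disk_scene(seed = 1, tt = 12, h = 32, w = 32, radius = 6)
  n_seeds <- 50
  res <- sapply(seq_len(n_seeds), function(s) {
    scene$rng_seed <- s
    ref <- generate_reference_sequence(scene)
    out <- c()
    for (p in c(0.1, 0.4)) {
      pred <- degrade_sequence(
        ref, list(aorta = degradation_config(flicker_dropout_prob = p)),
        seed = s)
      out <- c(out, temporal_consistency(pred, "aorta"),
               pixel_count_variation(pred, "aorta"))
    }
    out
  })
  means <- rowMeans(res)
  expect_gt(means[1], means[3])  # consistency falls with dropout
  expect_lt(means[2], means[4])  # count variation rises with dropout
})
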