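test_that("experience groups follow the case-count rules with precedence", {
  expect_identical(as.character(assign_experience_group(150, 0)), "expert")
  expect_identical(as.character(assign_experience_group(50, 200)),
                   "intermediate")
  expect_identical(as.character(assign_experience_group(0, 5)), "novice")
  # boundary cases
  expect_identical(as.character(assign_experience_group(100, 0)),
                   "intermediate")
  expect_identical(as.character(assign_experience_group(101, 0)), "expert")
  expect_identical(as.character(assign_experience_group(10, 10)), "novice")
  expect_identical(as.character(assign_experience_group(0, 11)),
                   "intermediate")
  expect_error(assign_experience_group(-1, 0), "non-negative")

  # every profile maps to exactly one group over a grid of counts
  grid <- expand.grid(p = c(0, 5, 10, 11, 50, 100, 101, 500),
                      a = c(0, 10, 11, 200))
  g <- assign_experience_group(grid$p, grid$a)
  expect_false(anyNA(g))
})

test_that("rating aggregation averages the selected participants", {
  samples <- tibble::tibble(video_id = c("v1", "v1"),
                            structure = c("a", "b"))
  recs <- dplyr::bind_rows(
    one_rater_records(samples, c(2, 4)),
    dplyr::mutate(one_rater_records(samples, c(4, 4)),
                  participant_id = "novice_01",
                  cases_performed = 0L, cases_assisted = 0L)
  )
  all_means <- aggregate_ratings(recs, "all")
  expect_equal(all_means$mean_rating[all_means$structure == "a"], 3)
  exp_means <- aggregate_ratings(recs, "expert")
  expect_equal(exp_means$mean_rating, c(2, 4))
  # group filter that excludes all records errors explicitly
  expect_error(aggregate_ratings(one_rater_records(samples, c(1, 2)),
                                 "novice"), "no ratings")
})

test_that("spearman_abs matches the closed form and handles ties", {
  expect_equal(spearman_abs(1:5, c(2, 4, 6, 7, 9)), 1)
  expect_equal(spearman_abs(1:5, -(1:5)), 1)          # absolute value
  expect_equal(spearman_abs(c(1, 2, 3), c(3, 1, 2)), 0.5)

  withr::with_seed(31, {
    for (i in 1:50) {
      x <- sample(100, 10)                  # untied
      y <- sample(100, 10)
      expect_equal(spearman_abs(x, y), abs(spearman_untied(x, y)),
                   tolerance = 1e-12)
    }
    for (i in 1:50) {
      x <- sample(5, 12, replace = TRUE)    # heavy ties
      y <- sample(5, 12, replace = TRUE)
      if (sd(x) == 0 || sd(y) == 0) next
      expect_equal(spearman_abs(x, y),
                   abs(cor(x, y, method = "spearman")), tolerance = 1e-12)
    }
  })

  expect_true(is.na(spearman_abs(rep(1, 5), 1:5)))    # constant -> undefined
  expect_error(spearman_abs(1:2, 1:2), "at least 3")
})

test_that("correlation tables are rank-invariant and order-invariant", {
  metrics <- toy_metric_table(n = 14, seed = 8)
  # a strictly increasing noiseless function of dice (rank works as a
  # synthetic Likert surrogate; only ranks matter downstream)
  ratings <- one_rater_records(metrics[, c("video_id", "structure")],
                               rank(metrics$dice))
  tab <- correlation_table(metrics, ratings, groups = "all")

  rho <- function(m) tab$abs_rho[tab$metric == m]
  # ratings are a monotone function of dice -> |rho| = 1
  expect_equal(rho("dice"), 1)
  # monotone metric pairs give bit-identical correlations
  expect_equal(rho("dice"), rho("iou"), tolerance = 1e-15)
  expect_equal(rho("sensitivity"), rho("fnr"), tolerance = 1e-15)

  # permuting sample order changes nothing
  perm <- withr::with_seed(2, sample(nrow(metrics)))
  tab2 <- correlation_table(metrics[perm, ], ratings, groups = "all")
  expect_equal(dplyr::arrange(tibble::as_tibble(tab2), metric),
               dplyr::arrange(tibble::as_tibble(tab), metric))

  expect_error(correlation_table(metrics[1:2, ], ratings, groups = "all"),
               "fewer than 3")
})

test_that("class-wise tables exclude small classes and report them", {
  base <- toy_metric_table(n = 9, seed = 5)
  metrics <- dplyr::mutate(base, structure = rep(c("airways", "esophagus",
                                                   "thoracic_duct"),
                                                 c(6, 1, 2)))
  ratings <- one_rater_records(metrics[, c("video_id", "structure")],
                               rank(metrics$dice))
  expect_message(
    tab <- classwise_correlation_table(metrics, ratings, eval_config()),
    "excluding 2 structure"
  )
  expect_setequal(attr(tab, "excluded"), c("esophagus", "thoracic_duct"))
  expect_setequal(unique(tab$structure), "airways")
  # noiseless monotone ratings within the kept class -> |rho| = 1
  expect_equal(tab$abs_rho[tab$metric == "dice"], 1)
})

test_that("identification vs accuracy Pearson matches hand computation", {
  mk <- function(acc, ident) {
    tibble::tibble(
      participant_id = "p1", cases_performed = 0L, cases_assisted = 0L,
      video_id = sprintf("v%d", seq_along(acc)), structure = "a",
      accuracy_rating = acc, identification_rating = ident
    )
  }
  expect_equal(usefulness_accuracy_pearson(mk(c(1L, 2L, 3L), c(1L, 2L, 3L))), 1)
  expect_equal(usefulness_accuracy_pearson(mk(c(1L, 2L, 3L), c(5L, 4L, 3L))), -1)
  r <- mk(c(1L, 2L, 3L), c(2L, 1L, 3L))
  expect_equal(usefulness_accuracy_pearson(r), cor(c(1, 2, 3), c(2, 1, 3)))
  expect_error(usefulness_accuracy_pearson(mk(c(2L, 2L, 2L), c(1L, 2L, 3L))),
               "constant")
})
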