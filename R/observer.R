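#' Assign experience groups from case counts
#'
#' Stratifies participants by surgical experience with the procedure:
#' experts have performed more than 100 cases (beyond the typical learning
#' curve), intermediates have performed or assisted more than 10 cases (but
#' performed at most 100), novices at most 10 performed and assisted. The
#' precedence expert > intermediate > novice resolves the overlap in the
#' textual definitions (a 150-case surgeon also satisfies the intermediate
#' wording).
#'
#' @param cases_performed,cases_assisted Non-negative integer vectors.
#' @return A factor with levels `expert`, `intermediate`, `novice`.
#' @export
#' @examples
#' assign_experience_group(c(150, 50, 0), c(0, 200, 5))
assign_experience_group <- function(cases_performed, cases_assisted) {
  if (any(cases_performed < 0) || any(cases_assisted < 0)) {
    stop("case counts must be non-negative", call. = FALSE)
  }
  out <- ifelse(cases_performed > 100, "expert",
                ifelse(cases_performed > 10 | cases_assisted > 10,
                       "intermediate", "novice"))
  factor(out, levels = c("expert", "intermediate", "novice"))
}

filter_group <- function(records, group) {
  if (identical(group, "all")) return(records)
  g <- assign_experience_group(records$cases_performed, records$cases_assisted)
  records[g == group, , drop = FALSE]
}

#' Mean accuracy rating per sample
#'
#' Averages the accuracy item over the selected participants for every
#' (video, structure) sample — the "average surgeon's rating" that the
#' metric battery is correlated against. Samples no selected participant
#' rated are omitted (not zero-filled).
#'
#' @param records Ratings tibble (see [read_ratings()]).
#' @param group `"all"` or one of `"expert"`, `"intermediate"`, `"novice"`;
#'   the pool is filtered by [assign_experience_group()] on the raw case
#'   counts.
#' @return Tibble `video_id`, `structure`, `mean_rating`, `n_raters`.
#' @export
aggregate_ratings <- function(records, group = "all") {
  sel <- filter_group(records, group)
  if (nrow(sel) == 0L) {
    stop("no ratings from group '", group, "'", call. = FALSE)
  }
  sel |>
    dplyr::group_by(.data$video_id, .data$structure) |>
    dplyr::summarise(mean_rating = mean(.data$accuracy_rating),
                     n_raters = dplyr::n(), .groups = "drop")
}

#' Absolute Spearman correlation
#'
#' `|rho|` where `rho` is the Pearson correlation of average ranks (ties
#' receive the mean of their rank positions). The absolute value is used
#' because several metrics are negatively oriented (error rates, distances):
#' only the strength of the monotone association is compared across
#' metrics. Undefined for constant input, which is reported as `NA` and
#' excluded from tables rather than coerced to 0.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return Value in `[0, 1]`, or `NA` when either input is constant.
#' @export
spearman_abs <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 paired samples", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  abs(stats::cor(rx, ry))
}

#' Metric-vs-rating correlation table
#'
#' The central analysis: for every metric and every rater group, the
#' absolute Spearman correlation between the per-sample metric values and
#' the group's mean accuracy ratings, over the intersection of samples
#' having both. Monotonically paired metrics (Dice/IoU,
#' sensitivity/FNR, specificity/FPR) yield identical entries by rank
#' invariance.
#'
#' @param metrics Wide tibble of per-sample metric vectors
#'   (from [evaluate_sequences()] rows): `video_id`, `structure`, one column
#'   per metric.
#' @param records Ratings tibble.
#' @param groups Character vector of groups; default
#'   `c("all", "expert", "intermediate", "novice")`.
#' @param config An [eval_config()].
#' @return A tibble of class `correlation_table`: `metric`, `group`,
#'   `abs_rho`, `n_samples`.
#' @export
correlation_table <- function(metrics, records,
                              groups = c("all", "expert", "intermediate", "novice"),
                              config = eval_config()) {
  mcols <- intersect(metric_names, names(metrics))
  if (length(mcols) == 0L) stop("no metric columns found", call. = FALSE)
  out <- purrr::map_dfr(groups, function(g) {
    means <- aggregate_ratings(records, g)
    joined <- dplyr::inner_join(metrics, means,
                                by = c("video_id", "structure"))
    if (nrow(joined) < 3L) {
      stop("fewer than 3 samples with both a metric value and a '", g,
           "' rating", call. = FALSE)
    }
    purrr::map_dfr(mcols, function(m) {
      ok <- !is.na(joined[[m]])
      n <- sum(ok)
      rho <- if (n >= 3L) spearman_abs(joined[[m]][ok], joined$mean_rating[ok])
             else NA_real_
      tibble::tibble(metric = m, group = g, abs_rho = rho, n_samples = n)
    })
  })
  class(out) <- c("correlation_table", class(out))
  out
}

#' Class-wise correlation table
#'
#' Correlations of each metric with the all-participant mean rating,
#' computed separately per anatomical structure. Structures with fewer than
#' `min_class_samples` samples are excluded (and recorded in the
#' `"excluded"` attribute): with one or two samples the rank correlation is
#' artificially perfect and meaningless.
#'
#' @inheritParams correlation_table
#' @return A tibble of class `correlation_table`: `metric`, `structure`,
#'   `abs_rho`, `n_samples`; excluded structures in `attr(, "excluded")`.
#' @export
classwise_correlation_table <- function(metrics, records,
                                        config = eval_config()) {
  mcols <- intersect(metric_names, names(metrics))
  means <- aggregate_ratings(records, "all")
  joined <- dplyr::inner_join(metrics, means, by = c("video_id", "structure"))
  counts <- dplyr::count(joined, .data$structure)
  excluded <- counts$structure[counts$n < config$min_class_samples]
  if (length(excluded) > 0) {
    message("excluding ", length(excluded), " structure(s) with fewer than ",
            config$min_class_samples, " samples: ",
            paste(excluded, collapse = ", "))
  }
  keep <- setdiff(counts$structure, excluded)
  out <- purrr::map_dfr(keep, function(s) {
    sub <- joined[joined$structure == s, , drop = FALSE]
    purrr::map_dfr(mcols, function(m) {
      ok <- !is.na(sub[[m]])
      n <- sum(ok)
      rho <- if (n >= 3L) spearman_abs(sub[[m]][ok], sub$mean_rating[ok])
             else NA_real_
      tibble::tibble(metric = m, structure = s, abs_rho = rho, n_samples = n)
    })
  })
  attr(out, "excluded") <- excluded
  class(out) <- c("correlation_table", class(out))
  out
}

#' Pearson correlation of identification vs. accuracy responses
#'
#' Whether overlays rated as more accurate are also judged to help
#' structure identification more: the Pearson correlation between the
#' per-video mean identification-improvement rating and the per-video mean
#' accuracy rating, over all participants.
#'
#' @param records Ratings tibble.
#' @return Pearson r in `[-1, 1]`.
#' @export
usefulness_accuracy_pearson <- function(records) {
  means <- records |>
    dplyr::group_by(.data$video_id) |>
    dplyr::summarise(acc = mean(.data$accuracy_rating),
                     ident = mean(.data$identification_rating),
                     .groups = "drop")
  if (nrow(means) < 3L) stop("need at least 3 videos", call. = FALSE)
  if (stats::sd(means$acc) == 0 || stats::sd(means$ident) == 0) {
    stop("per-video means are constant; Pearson r undefined", call. = FALSE)
  }
  stats::cor(means$ident, means$acc)
}
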