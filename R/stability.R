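#' Ranking-stability configuration
#'
#' @param n_bootstrap Number of bootstrap replicates `B`. Default 1000.
#' @param subsample_size Samples drawn per replicate `m`, without
#'   replacement (default 35 of the study's 46 samples, about 75%):
#'   drawing distinct structures implies subsets rather than classical
#'   with-replacement resampling.
#' @param rng_seed Integer seed.
#' @return An object of class `stability_config`.
#' @export
stability_config <- function(n_bootstrap = 1000L, subsample_size = 35L,
                             rng_seed = 1L) {
  stopifnot(n_bootstrap >= 1, subsample_size >= 3)
  structure(
    list(n_bootstrap = as.integer(n_bootstrap),
         subsample_size = as.integer(subsample_size),
         rng_seed = as.integer(rng_seed)),
    class = "stability_config"
  )
}

#' Bootstrap ranking stability of metrics
#'
#' How reliably does each metric keep its position when the evaluation set
#' changes? For each of `B` replicates, `m` samples are drawn without
#' replacement, the absolute Spearman correlation with the mean rating is
#' recomputed per metric on the subsample, and metrics are ranked descending
#' by `|rho|` (rank 1 = strongest association; ties get average ranks). A
#' metric whose correlation is undefined on a replicate (constant values)
#' receives the worst rank of that replicate.
#'
#' @param metrics Wide per-sample metric tibble (see [correlation_table()]).
#' @param ratings Per-sample mean ratings: output of [aggregate_ratings()]
#'   (all participants, as the analysis is not stratified), or a raw ratings
#'   tibble which is aggregated internally.
#' @param cfg A [stability_config()].
#' @return An object of class `rank_distribution`: list with `ranks`
#'   (`B x M` matrix, one column per metric) and `summary` (tibble `metric`,
#'   `median_rank`, `mean_rank`, `iqr_rank`, `mean_abs_rho`).
#' @export
bootstrap_ranks <- function(metrics, ratings, cfg = stability_config()) {
  if ("accuracy_rating" %in% names(ratings)) {
    ratings <- aggregate_ratings(ratings, "all")
  }
  joined <- dplyr::inner_join(metrics, ratings, by = c("video_id", "structure"))
  n <- nrow(joined)
  m <- cfg$subsample_size
  if (m > n) stop("subsample size ", m, " exceeds ", n, " samples", call. = FALSE)
  mcols <- intersect(metric_names, names(metrics))
  mm <- as.matrix(joined[, mcols, drop = FALSE])
  rating <- joined$mean_rating
  withr::local_seed(derive_seed(cfg$rng_seed, "bootstrap"))
  ranks <- matrix(NA_real_, cfg$n_bootstrap, length(mcols),
                  dimnames = list(NULL, mcols))
  rho_acc <- matrix(NA_real_, cfg$n_bootstrap, length(mcols))
  for (b in seq_len(cfg$n_bootstrap)) {
    idx <- sample.int(n, m, replace = FALSE)
    rho <- vapply(seq_along(mcols), function(j) {
      v <- mm[idx, j]
      ok <- !is.na(v)
      if (sum(ok) < 3L) return(NA_real_)
      rv <- rank(v[ok])
      rsub <- rank(rating[idx][ok])
      if (stats::sd(rv) == 0 || stats::sd(rsub) == 0) return(NA_real_)
      abs(stats::cor(rv, rsub))
    }, numeric(1))
    rho_acc[b, ] <- rho
    # undefined |rho| -> worst: rank with -Inf keeps average-rank permutation
    rho[is.na(rho)] <- -Inf
    ranks[b, ] <- rank(-rho, ties.method = "average")
  }
  summary <- tibble::tibble(
    metric = mcols,
    median_rank = apply(ranks, 2, stats::median),
    mean_rank = colMeans(ranks),
    iqr_rank = apply(ranks, 2, stats::IQR),
    mean_abs_rho = colMeans(rho_acc, na.rm = TRUE)
  )
  structure(list(ranks = ranks, summary = summary, config = cfg),
            class = "rank_distribution")
}

#' @export
print.rank_distribution <- function(x, ...) {
  cat(sprintf("<rank_distribution: %d metrics x %d bootstrap replicates>\n",
              ncol(x$ranks), nrow(x$ranks)))
  print(x$summary[order(x$summary$median_rank, x$summary$mean_rank), ])
  invisible(x)
}

#' Order metrics by ranking stability
#'
#' Best metric first: ascending median rank across bootstrap replicates,
#' ties broken by mean rank, remaining ties alphabetically for determinism.
#'
#' @param dist A `rank_distribution` from [bootstrap_ranks()].
#' @return Character vector of metric names, best first.
#' @export
order_metrics <- function(dist) {
  s <- dist$summary
  s$metric[order(s$median_rank, s$mean_rank, s$metric)]
}

#' @export
tidy.rank_distribution <- function(x, ...) {
  tibble::as_tibble(x$ranks) |>
    dplyr::mutate(replicate = dplyr::row_number()) |>
    tidyr::pivot_longer(-"replicate", names_to = "metric", values_to = "rank")
}

#' @export
glance.rank_distribution <- function(x, ...) {
  best <- order_metrics(x)[1]
  tibble::tibble(
    n_metrics = ncol(x$ranks), n_bootstrap = nrow(x$ranks),
    subsample_size = x$config$subsample_size,
    best_metric = best,
    best_median_rank = x$summary$median_rank[x$summary$metric == best]
  )
}

#' @export
tidy.correlation_table <- function(x, ...) {
  out <- tibble::as_tibble(x)
  attr(out, "excluded") <- NULL
  out
}

#' @export
glance.correlation_table <- function(x, ...) {
  ok <- !is.na(x$abs_rho)
  tibble::tibble(
    n_entries = nrow(x), n_undefined = sum(!ok),
    max_abs_rho = max(x$abs_rho[ok]),
    best_metric = x$metric[ok][which.max(x$abs_rho[ok])]
  )
}

#' Dot plot of bootstrap rank distributions
#'
#' One column per metric (best, by median-then-mean rank, on the left), one
#' jittered dot per bootstrap replicate, with the median rank marked.
#'
#' @param object A `rank_distribution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rank_distribution <- function(object, ...) {
  long <- tidy.rank_distribution(object)
  long$metric <- factor(long$metric, levels = order_metrics(object))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$rank)) +
    ggplot2::geom_jitter(width = 0.25, height = 0.15, alpha = 0.08, size = 0.6) +
    ggplot2::stat_summary(fun = stats::median, geom = "point",
                          colour = "red", size = 2) +
    ggplot2::labs(x = NULL, y = "rank across bootstrap replicates",
                  title = "Metric ranking stability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heat-map of a correlation table
#'
#' Metrics on the y axis, groups (or structures for the class-wise table) on
#' the x axis, tile fill = absolute Spearman correlation; undefined entries
#' are blank.
#'
#' @param object A `correlation_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.correlation_table <- function(object, ...) {
  xvar <- if ("group" %in% names(object)) "group" else "structure"
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[xvar]], y = .data$metric,
                                   fill = .data$abs_rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$abs_rho), "", sprintf("%.2f", .data$abs_rho))),
      size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "|rho|",
                  title = "Absolute Spearman correlation with mean ratings") +
    ggplot2::theme_minimal()
}
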