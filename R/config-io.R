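#' Write a pipeline configuration to YAML
#'
#' Serializes every section of a [pipeline_config()] — scene dimensions,
#' structure geometry, sample allocation, per-sample degradations, rater
#' panel, metric and bootstrap settings — into one YAML file that
#' [read_pipeline_config()] reconstructs exactly.
#'
#' @param config A [pipeline_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  as_plain <- function(x) lapply(x, function(v) if (is.null(v)) NULL else v)
  obj <- list(
    n_videos = config$n_videos,
    frames_per_video = config$frames_per_video,
    height = config$height, width = config$width,
    seed = config$seed, apply_smoothing = config$apply_smoothing,
    geometry = lapply(seq_len(nrow(config$geometry)),
                      function(i) as.list(config$geometry[i, ])),
    allocation = lapply(seq_len(nrow(config$allocation)),
                        function(i) as.list(config$allocation[i, ])),
    degradations = lapply(config$degradations, as_plain),
    raters = lapply(config$raters, unclass),
    eval = unclass(config$eval),
    stability = unclass(config$stability)
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file written by [write_pipeline_config()] (or authored
#'   by hand with the same sections). Missing `eval`/`stability`/`raters`
#'   sections fall back to package defaults.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  degr <- lapply(obj$degradations, function(d) {
    do.call(degradation_config, d[!vapply(d, is.null, logical(1))])
  })
  raters <- if (is.null(obj$raters)) default_rater_groups() else {
    lapply(obj$raters, function(r) do.call(rater_group_config, r))
  }
  eval <- if (is.null(obj$eval)) eval_config() else do.call(eval_config, obj$eval)
  stab <- if (is.null(obj$stability)) stability_config() else {
    do.call(stability_config, obj$stability)
  }
  pipeline_config(
    n_videos = obj$n_videos, frames_per_video = obj$frames_per_video,
    height = obj$height, width = obj$width,
    geometry = dplyr::bind_rows(obj$geometry),
    allocation = dplyr::bind_rows(obj$allocation),
    degradations = degr, raters = raters, eval = eval, stability = stab,
    apply_smoothing = isTRUE(obj$apply_smoothing),
    seed = if (is.null(obj$seed)) 1L else obj$seed
  )
}
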