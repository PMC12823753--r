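#' Rater-group configuration
#'
#' Behavioral model for one experience stratum of the simulated rater panel.
#' Each rater maps a sample's latent quality `q` in `[0, 1]` to a Likert
#' rating via
#' `clamp(round(L_min + (L_max - L_min) * (leniency + sensitivity * q) + e))`
#' with Gaussian noise `e ~ N(0, noise_sd)`. Leniency shifts ratings upward
#' regardless of quality; sensitivity is the slope on quality, so a
#' low-sensitivity group discriminates less between good and bad overlays.
#' The defaults encode the empirical pattern that novices rate more
#' leniently and less discriminatively than experts.
#'
#' @param group One of `"expert"`, `"intermediate"`, `"novice"`.
#' @param n_raters Number of raters in the group.
#' @param leniency Additive offset on the unit quality scale.
#' @param sensitivity Slope on latent quality.
#' @param noise_sd Rating noise standard deviation, in Likert-scale units
#'   (the noise is added after scaling quality to the Likert range).
#' @param cases_performed_range,cases_assisted_range Integer `(lo, hi)`
#'   ranges the simulated case counts are drawn from; they must be
#'   consistent with the group's experience definition (expert: more than
#'   100 cases performed; novice: at most 10 performed and assisted).
#' @return An object of class `rater_group_config`.
#' @export
rater_group_config <- function(group, n_raters, leniency = 0, sensitivity = 1,
                               noise_sd = 0.1,
                               cases_performed_range = NULL,
                               cases_assisted_range = NULL) {
  group <- match.arg(group, c("expert", "intermediate", "novice"))
  defaults <- list(
    expert = list(perf = c(101L, 400L), assist = c(0L, 400L)),
    intermediate = list(perf = c(11L, 100L), assist = c(0L, 200L)),
    novice = list(perf = c(0L, 10L), assist = c(0L, 10L))
  )[[group]]
  if (is.null(cases_performed_range)) cases_performed_range <- defaults$perf
  if (is.null(cases_assisted_range)) cases_assisted_range <- defaults$assist
  stopifnot(n_raters >= 1, noise_sd >= 0,
            length(cases_performed_range) == 2L,
            length(cases_assisted_range) == 2L)
  cfg <- structure(
    list(group = group, n_raters = as.integer(n_raters),
         leniency = leniency, sensitivity = sensitivity, noise_sd = noise_sd,
         cases_performed_range = as.integer(cases_performed_range),
         cases_assisted_range = as.integer(cases_assisted_range)),
    class = "rater_group_config"
  )
  probe <- expand.grid(p = cases_performed_range, a = cases_assisted_range)
  got <- assign_experience_group(probe$p, probe$a)
  if (!all(got == group)) {
    stop("case-count ranges are inconsistent with group '", group, "'",
         call. = FALSE)
  }
  cfg
}

#' Default rater panel
#'
#' The study's stratified panel: 7 experts (sensitivity 1.0, no leniency,
#' noise sd 0.08), 11 intermediates (intermediate behavior), and 8 novices
#' (sensitivity 0.4, leniency 0.5, noise sd 0.2) — novices rate higher on
#' average and track quality less closely.
#'
#' @return A list of three [rater_group_config()] objects.
#' @export
default_rater_groups <- function() {
  list(
    rater_group_config("expert", 7L, leniency = 0, sensitivity = 1.0,
                       noise_sd = 0.08),
    rater_group_config("intermediate", 11L, leniency = 0.25, sensitivity = 0.7,
                       noise_sd = 0.15),
    rater_group_config("novice", 8L, leniency = 0.5, sensitivity = 0.4,
                       noise_sd = 0.2)
  )
}

#' Simulate a rater panel over study samples
#'
#' Every rater of every group rates every sample: the accuracy item from the
#' group's response model applied to the sample's latent quality, and the
#' identification-improvement item from the same model with independent
#' noise. Participant experience profiles are drawn uniformly from the
#' group's case-count ranges. Deterministic given `seed`.
#'
#' @param quality Data frame with columns `video_id`, `structure`, `quality`
#'   (latent quality in `[0, 1]`, typically the sample's Dice score).
#' @param groups List of [rater_group_config()]; default
#'   [default_rater_groups()].
#' @param config An [eval_config()] supplying the Likert bounds.
#' @param seed Integer seed.
#' @return A tibble in the ratings-table schema (see [read_ratings()]).
#' @export
simulate_ratings <- function(quality, groups = default_rater_groups(),
                             config = eval_config(), seed = 1L) {
  quality <- tibble::as_tibble(quality)
  stopifnot(all(c("video_id", "structure", "quality") %in% names(quality)))
  if (any(quality$quality < 0 | quality$quality > 1)) {
    stop("latent quality must lie in [0, 1]", call. = FALSE)
  }
  lmin <- config$likert_min
  lmax <- config$likert_max
  span <- lmax - lmin
  withr::local_seed(derive_seed(seed, "raters"))
  n_s <- nrow(quality)
  purrr::map_dfr(groups, function(g) {
    purrr::map_dfr(seq_len(g$n_raters), function(r) {
      perf <- sample(g$cases_performed_range[1]:g$cases_performed_range[2], 1L)
      assist <- sample(g$cases_assisted_range[1]:g$cases_assisted_range[2], 1L)
      latent <- g$leniency + g$sensitivity * quality$quality
      rate_once <- function() {
        raw <- round(lmin + span * latent + stats::rnorm(n_s, 0, g$noise_sd))
        as.integer(pmin(pmax(raw, lmin), lmax))
      }
      tibble::tibble(
        participant_id = sprintf("%s_%02d", g$group, r),
        cases_performed = perf, cases_assisted = assist,
        video_id = quality$video_id, structure = quality$structure,
        accuracy_rating = rate_once(),
        identification_rating = rate_once()
      )
    })
  })
}
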