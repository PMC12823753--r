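#' Write a label sequence to disk
#'
#' Stores each frame as a lossless single-channel 8-bit PNG (gray value =
#' label id) plus a `sequence_manifest.json` recording `video_id`, `fps`,
#' `class_names` and the ordered frame file list. [read_label_sequence()]
#' inverts this bit-exactly. PNG is used instead of a video container to
#' avoid codec nondeterminism.
#'
#' @param seq A [label_sequence()]. At most 256 classes are supported by the
#'   8-bit encoding.
#' @param dir Directory to write into (created if absent).
#' @return The manifest path, invisibly usable as input to
#'   [read_label_sequence()].
#' @export
write_label_sequence <- function(seq, dir) {
  stopifnot(inherits(seq, "label_sequence"))
  if (length(seq$class_names) > 256L) {
    stop("8-bit frame encoding supports at most 256 classes", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir, call. = FALSE)
  tt <- n_frames(seq)
  files <- sprintf("frame_%04d.png", seq_len(tt))
  for (t in seq_len(tt)) {
    png::writePNG(seq$frames[, , t] / 255, file.path(dir, files[t]))
  }
  manifest <- file.path(dir, "sequence_manifest.json")
  jsonlite::write_json(
    list(video_id = seq$video_id, fps = seq$fps,
         class_names = seq$class_names, frame_files = files),
    manifest, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(manifest)
}

#' Read a label sequence from a manifest
#'
#' @param manifest_path Path to a `sequence_manifest.json` written by
#'   [write_label_sequence()] (or assembled by hand with the same fields).
#' @return A [label_sequence()]. Frames are loaded in manifest order and
#'   validated: all frames must share one shape and no label may reach
#'   `length(class_names)`.
#' @export
read_label_sequence <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  for (f in c("video_id", "class_names", "frame_files")) {
    if (is.null(m[[f]])) stop("manifest missing field: ", f, call. = FALSE)
  }
  dir <- dirname(manifest_path)
  paths <- file.path(dir, m$frame_files)
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("missing frame file(s): ", paste(m$frame_files[missing], collapse = ", "),
         call. = FALSE)
  }
  frames <- NULL
  for (t in seq_along(paths)) {
    img <- png::readPNG(paths[t])
    if (length(dim(img)) == 3L) img <- img[, , 1]
    lab <- round(img * 255)
    if (is.null(frames)) {
      frames <- array(0L, c(dim(lab), length(paths)))
    } else if (!identical(dim(lab), dim(frames)[1:2])) {
      stop("frame ", m$frame_files[t], " has inconsistent shape", call. = FALSE)
    }
    frames[, , t] <- as.integer(lab)
  }
  if (max(frames) >= length(m$class_names)) {
    stop("frame contains label id ", max(frames), " but only ",
         length(m$class_names), " classes are declared", call. = FALSE)
  }
  label_sequence(frames, m$class_names, m$video_id,
                 if (is.null(m$fps)) 25 else m$fps)
}

ratings_columns <- c("participant_id", "cases_performed", "cases_assisted",
                     "video_id", "structure", "accuracy_rating",
                     "identification_rating")

#' Read a ratings table
#'
#' Parses the survey CSV: one row per (participant, video, structure) with
#' the participant's experience profile as raw case counts and two Likert
#' items (perceived annotation accuracy; improvement in structure
#' identification). Rows violating the declared scale bounds raise an error
#' rather than being coerced.
#'
#' @param csv_path CSV with exactly the columns `participant_id`,
#'   `cases_performed`, `cases_assisted`, `video_id`, `structure`,
#'   `accuracy_rating`, `identification_rating`.
#' @param config An [eval_config()] supplying the Likert bounds.
#' @return A tibble of rating records.
#' @export
read_ratings <- function(csv_path, config = eval_config()) {
  df <- readr::read_csv(csv_path, show_col_types = FALSE,
                        col_types = readr::cols(
                          participant_id = readr::col_character(),
                          cases_performed = readr::col_integer(),
                          cases_assisted = readr::col_integer(),
                          video_id = readr::col_character(),
                          structure = readr::col_character(),
                          accuracy_rating = readr::col_integer(),
                          identification_rating = readr::col_integer()
                        ))
  validate_ratings(df, config)
}

validate_ratings <- function(df, config) {
  extra <- setdiff(names(df), ratings_columns)
  if (length(extra) > 0) {
    stop("unknown column(s): ", paste(extra, collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(ratings_columns, names(df))
  if (length(miss) > 0) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyNA(df)) stop("malformed row: missing values in ratings table", call. = FALSE)
  if (any(df$cases_performed < 0) || any(df$cases_assisted < 0)) {
    stop("case counts must be non-negative", call. = FALSE)
  }
  for (col in c("accuracy_rating", "identification_rating")) {
    bad <- df[[col]] < config$likert_min | df[[col]] > config$likert_max
    if (any(bad)) {
      stop(sum(bad), " ", col, " value(s) outside the Likert scale [",
           config$likert_min, ", ", config$likert_max, "]", call. = FALSE)
    }
  }
  tibble::as_tibble(df)
}

#' Write a results table as CSV
#'
#' Deterministic serialization used for all pipeline artifacts: column order
#' is preserved, numeric columns are rendered at a fixed decimal precision so
#' identical runs produce byte-identical files.
#'
#' @param df Data frame with homogeneous columns.
#' @param path Output CSV path.
#' @param digits Decimal places for non-integer numeric columns. Default 6.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path, digits = 6) {
  stopifnot(is.data.frame(df))
  out <- as.data.frame(df)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), NA_character_,
                         sprintf(paste0("%.", digits, "f"), out[[j]]))
    }
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}
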