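# Ingest module: read, validate and merge detection-trial tables and
# hazardousness-rating tables into the single analysis table keyed by
# movie. File dialects vary between deposits, so all readers take a
# column map; the synthetic schema is the default.

#' Default column maps for the trial and rating schemas
#'
#' @return named character vector mapping canonical names to file column
#'   names.
#' @export
default_trial_columns <- function() {
  c(participant_id = "participant_id", experiment_id = "experiment_id",
    prevalence_condition = "prevalence_condition",
    session_order = "session_order", movie_id = "movie_id",
    hazard_present = "hazard_present", response_yes = "response_yes")
}

#' @rdname default_trial_columns
#' @export
default_rating_columns <- function() {
  c(rater_id = "rater_id", movie_id = "movie_id", rating = "rating")
}

#' Load report attached to ingested tables
#'
#' Readers attach a report listing row counts and dropped rows with
#' reasons; `load_report()` retrieves it.
#'
#' @param x a table returned by [read_trials()], [read_ratings()] or
#'   [merge_trials_ratings()].
#' @return list with `n_rows`, `n_kept`, `n_dropped` and a `dropped`
#'   data.frame (`row`, `reason`).
#' @export
load_report <- function(x) attr(x, "load_report")

make_report <- function(n_rows, kept, dropped_rows, reasons) {
  list(n_rows = n_rows, n_kept = kept,
       n_dropped = length(dropped_rows),
       dropped = data.frame(row = dropped_rows, reason = reasons,
                            stringsAsFactors = FALSE))
}

read_delim_guess <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "",
                    fileEncoding = "UTF-8", check.names = FALSE)
}

check_columns <- function(raw, column_map, path) {
  missing <- setdiff(unname(column_map), names(raw))
  if (length(missing))
    stop_input("missing mapped column(s) ", paste(missing, collapse = ", "),
               " in ", path, "; available columns: ",
               paste(names(raw), collapse = ", "))
}

parse_logical <- function(x) {
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[v %in% c("false", "f", "0", "no", "n")] <- FALSE
  out
}

parse_condition <- function(x) {
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(v))
  out[v %in% c("high", "h")] <- "high"
  out[v %in% c("low", "l")] <- "low"
  out
}

#' Read a trial-level detection table
#'
#' Parses a delimited text file (comma or tab, header required) of
#' detection trials with explicit type coercion. Rows with an unparseable
#' prevalence condition or response are dropped and recorded in the load
#' report rather than silently discarded.
#'
#' @param path file path.
#' @param column_map named character vector mapping the canonical names of
#'   [default_trial_columns()] to the file's column names; `session_order`
#'   is optional.
#' @return data.frame of trials with a `load_report` attribute.
#' @export
read_trials <- function(path, column_map = default_trial_columns()) {
  raw <- read_delim_guess(path)
  cm <- utils::modifyList(as.list(default_trial_columns()),
                          as.list(column_map))
  required <- setdiff(names(default_trial_columns()), "session_order")
  check_columns(raw, unlist(cm[required]), path)
  has_order <- cm$session_order %in% names(raw)

  out <- data.frame(
    participant_id = trimws(as.character(raw[[cm$participant_id]])),
    experiment_id = trimws(as.character(raw[[cm$experiment_id]])),
    prevalence_condition = parse_condition(raw[[cm$prevalence_condition]]),
    session_order = if (has_order)
      trimws(as.character(raw[[cm$session_order]])) else NA_character_,
    movie_id = trimws(as.character(raw[[cm$movie_id]])),
    hazard_present = parse_logical(raw[[cm$hazard_present]]),
    response_yes = parse_logical(raw[[cm$response_yes]]),
    stringsAsFactors = FALSE
  )

  bad_cond <- is.na(out$prevalence_condition)
  bad_resp <- is.na(out$response_yes)
  bad_truth <- is.na(out$hazard_present)
  bad <- bad_cond | bad_resp | bad_truth
  reasons <- character(0)
  if (any(bad)) {
    reasons <- ifelse(bad_cond[bad], "unparseable prevalence_condition",
                      ifelse(bad_resp[bad], "missing/unparseable response",
                             "missing/unparseable hazard_present"))
  }
  report <- make_report(nrow(raw), sum(!bad), which(bad), reasons)
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL

  dup <- duplicated(out[c("participant_id", "prevalence_condition",
                          "movie_id")])
  if (any(dup))
    warning(sum(dup), " duplicate (participant, condition, movie) rows ",
            "kept", call. = FALSE)
  structure(out, load_report = report)
}

#' Read a per-rater hazardousness rating table
#'
#' As [read_trials()], for the rating schema; additionally rejects (drops
#' and reports) ratings outside \[0, 1\].
#'
#' @param path file path.
#' @param column_map named character vector mapping
#'   [default_rating_columns()] names to the file's column names.
#' @return data.frame of ratings with a `load_report` attribute.
#' @export
read_ratings <- function(path, column_map = default_rating_columns()) {
  raw <- read_delim_guess(path)
  cm <- utils::modifyList(as.list(default_rating_columns()),
                          as.list(column_map))
  check_columns(raw, unlist(cm), path)

  out <- data.frame(
    rater_id = trimws(as.character(raw[[cm$rater_id]])),
    movie_id = trimws(as.character(raw[[cm$movie_id]])),
    rating = suppressWarnings(as.numeric(raw[[cm$rating]])),
    stringsAsFactors = FALSE
  )
  bad_na <- is.na(out$rating)
  bad_range <- !bad_na & (out$rating < 0 | out$rating > 1)
  bad <- bad_na | bad_range
  reasons <- ifelse(bad_na[bad], "missing/unparseable rating",
                    "rating outside [0, 1]")
  report <- make_report(nrow(raw), sum(!bad), which(bad), reasons)
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, load_report = report)
}

#' Per-movie median hazardousness ratings
#'
#' For an even number of ratings the median is the mean of the two middle
#' order statistics (the [stats::median()] convention).
#'
#' @param ratings data.frame of rating records (`movie_id`, `rating`).
#' @return data.frame with `movie_id`, `median_rating`, `n_ratings`.
#' @export
compute_median_ratings <- function(ratings) {
  if (is.null(ratings) || nrow(ratings) == 0)
    stop_input("no ratings supplied")
  med <- tapply(ratings$rating, ratings$movie_id, stats::median)
  n <- tapply(ratings$rating, ratings$movie_id, length)
  out <- data.frame(movie_id = names(med),
                    median_rating = as.numeric(med),
                    n_ratings = as.integer(n),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Merge trials with per-movie median ratings and quartile labels
#'
#' Inner join on `movie_id` (case-sensitive, whitespace already trimmed at
#' read time). Trials whose movie has no median are dropped and reported.
#' Hazard-present movies additionally receive a hazardousness quartile
#' label (Q1 least hazardous .. Q4 most hazardous) computed from the
#' medians of the hazard-present movies present in the median table (see
#' [assign_quartiles()]); hazard-absent trials get quartile `"none"`.
#'
#' @param trials trial data.frame (see [read_trials()]).
#' @param medians per-movie medians (see [compute_median_ratings()]).
#' @param quartiles optional precomputed [assign_quartiles()] result; by
#'   default quartiles are computed from `medians` restricted to the
#'   movies that are hazard-present in `trials`.
#' @return merged analysis table with `median_rating` and `quartile`
#'   columns and a `load_report` attribute.
#' @export
merge_trials_ratings <- function(trials, medians, quartiles = NULL) {
  if (is.null(trials) || nrow(trials) == 0) stop_input("no trials supplied")
  if (is.null(medians) || nrow(medians) == 0) stop_input("no medians supplied")
  med_lookup <- stats::setNames(medians$median_rating, medians$movie_id)
  hit <- trials$movie_id %in% names(med_lookup)
  if (!any(hit))
    stop_input("no trial movie_id matches the rating table; ",
               "check for an ID-format mismatch between the files")
  report <- make_report(nrow(trials), sum(hit), which(!hit),
                        rep("movie has no median rating", sum(!hit)))
  out <- trials[hit, , drop = FALSE]
  out$median_rating <- unname(med_lookup[out$movie_id])

  if (is.null(quartiles)) {
    present_movies <- unique(out$movie_id[out$hazard_present])
    if (length(present_movies) >= 4) {
      quartiles <- assign_quartiles(
        medians[medians$movie_id %in% present_movies, , drop = FALSE])
    }
  }
  out$quartile <- "none"
  if (!is.null(quartiles)) {
    qmap <- stats::setNames(quartiles$map$quartile, quartiles$map$movie_id)
    idx <- out$hazard_present & out$movie_id %in% names(qmap)
    out$quartile[idx] <- unname(qmap[out$movie_id[idx]])
  }
  rownames(out) <- NULL
  structure(out, load_report = report)
}

#' Write / read a merged analysis table
#'
#' Plain-CSV serialization that round-trips the merged table exactly
#' (column types re-coerced on read).
#'
#' @param table merged table from [merge_trials_ratings()].
#' @param path CSV path.
#' @return `read_merged()` returns the merged table.
#' @export
write_merged <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_merged
#' @export
read_merged <- function(path) {
  out <- read_delim_guess(path)
  out$hazard_present <- parse_logical(out$hazard_present)
  out$response_yes <- parse_logical(out$response_yes)
  out$median_rating <- as.numeric(out$median_rating)
  for (col in c("participant_id", "experiment_id", "prevalence_condition",
                "session_order", "movie_id", "quartile"))
    out[[col]] <- as.character(out[[col]])
  out
}
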