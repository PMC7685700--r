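#' Validate an activity-event table
#'
#' Checks the canonical event schema: a second-precision timestamp, a
#' platform and action from the closed vocabularies (`google_search`,
#' `youtube`; `search_query`, `url_visit`, `video_watch`, `youtube_search`),
#' and the constraint that watch/search actions on the video platform imply
#' `platform == "youtube"`. Events are re-sorted by participant and time with
#' a warning if they arrive unsorted; ties at the same second keep their
#' input order.
#'
#' @param events A data frame with columns `participant_id`, `timestamp`,
#'   `platform`, `action`, and optionally `text` and `url`.
#' @return A validated tibble with `text`/`url` filled with `""` if absent.
#' @export
validate_events <- function(events) {
  events <- as_tibble(events)
  need <- c("participant_id", "timestamp", "platform", "action")
  miss <- setdiff(need, names(events))
  if (length(miss)) abort(paste("events missing columns:", paste(miss, collapse = ", ")))
  if (!inherits(events$timestamp, "POSIXct")) {
    abort("`timestamp` must be POSIXct; use read_events() to parse text logs")
  }
  if (anyNA(events$timestamp)) abort("events contain NA timestamps")
  bad_p <- setdiff(unique(events$platform), PLATFORMS)
  if (length(bad_p)) abort(paste0("unknown platform token(s): ", paste(bad_p, collapse = ", ")))
  bad_a <- setdiff(unique(events$action), ACTIONS)
  if (length(bad_a)) abort(paste0("unknown action token(s): ", paste(bad_a, collapse = ", ")))
  off <- events$action %in% YOUTUBE_ACTIONS & events$platform != "youtube"
  if (any(off)) abort("video_watch/youtube_search events must have platform 'youtube'")
  if (is.null(events$text)) events$text <- ""
  if (is.null(events$url)) events$url <- ""
  events$text[is.na(events$text)] <- ""
  events$url[is.na(events$url)] <- ""
  o <- order(events$participant_id, events$timestamp)
  if (is.unsorted(o)) {
    warn("events were not sorted by participant and time; re-sorting")
    events <- events[o, ]
  }
  events
}

# RFC-3339 with numeric offset, e.g. 2020-01-01T22:15:03-05:00
format_rfc3339 <- function(ts, tz) {
  s <- format(with_tz(ts, tz), "%Y-%m-%dT%H:%M:%S%z")
  sub("([+-][0-9]{2})([0-9]{2})$", "\\1:\\2", s)
}

parse_rfc3339 <- function(x) {
  y <- sub("Z$", "+0000", x)
  y <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", y)
  out <- as.POSIXct(y, format = "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
  out
}

#' Read and write activity-event logs
#'
#' The canonical on-disk schema is JSONL (one event object per line) with
#' fields `participant_id`, `timestamp` (RFC-3339 with explicit UTC offset),
#' `platform`, `action`, `text`, `url`. A CSV dialect with identical header
#' names is also supported. Malformed rows are reported with their line
#' numbers; unknown platform/action tokens and unparseable timestamps are
#' hard errors.
#'
#' @param path File path.
#' @param dialect `"jsonl"` or `"csv"`; guessed from the file extension by
#'   default.
#' @return `read_events()` returns a validated event tibble (timestamps as
#'   POSIXct instants, displayed in UTC); `write_events()` returns `path`
#'   invisibly.
#' @export
read_events <- function(path, dialect = c("auto", "jsonl", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (dialect == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- vector("list", length(lines))
    bad <- integer(0)
    for (i in seq_along(lines)) {
      row <- tryCatch(jsonlite::fromJSON(lines[[i]]), error = function(e) NULL)
      if (is.null(row) || !is.list(row)) bad <- c(bad, i) else rows[[i]] <- row
    }
    if (length(bad)) {
      abort(paste0("malformed JSONL row(s) at line(s): ", paste(bad, collapse = ", ")))
    }
    df <- tibble(
      participant_id = map_chr_default(rows, "participant_id"),
      timestamp_raw = map_chr_default(rows, "timestamp"),
      platform = map_chr_default(rows, "platform"),
      action = map_chr_default(rows, "action"),
      text = map_chr_default(rows, "text"),
      url = map_chr_default(rows, "url")
    )
  } else {
    df <- as_tibble(utils::read.csv(path, colClasses = "character"))
    names(df)[names(df) == "timestamp"] <- "timestamp_raw"
  }
  ts <- parse_rfc3339(df$timestamp_raw)
  if (anyNA(ts)) {
    bad <- which(is.na(ts))
    abort(paste0(
      "unparseable timestamp(s) at row(s) ", paste(head(bad, 10), collapse = ", "),
      ": expected RFC-3339 with offset, e.g. 2020-01-01T22:15:03-05:00"
    ))
  }
  df$timestamp <- ts
  df$timestamp_raw <- NULL
  validate_events(df)
}

map_chr_default <- function(rows, field, default = "") {
  vapply(rows, function(r) {
    v <- r[[field]]
    if (is.null(v) || length(v) != 1 || is.na(v)) default else as.character(v)
  }, character(1))
}

#' @rdname read_events
#' @param events A validated event tibble.
#' @param tz Timezone whose UTC offset is written into the timestamps.
#' @export
write_events <- function(events, path, dialect = c("auto", "jsonl", "csv"),
                         tz = "America/New_York") {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  events <- validate_events(events)
  out <- events |>
    mutate(timestamp = format_rfc3339(.data$timestamp, tz)) |>
    select("participant_id", "timestamp", "platform", "action", "text", "url")
  if (dialect == "jsonl") {
    lines <- vapply(seq_len(nrow(out)), function(i) {
      jsonlite::toJSON(as.list(out[i, ]), auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path)
  } else {
    utils::write.csv(out, path, row.names = FALSE)
  }
  invisible(path)
}

#' Build and validate a two-wave survey panel
#'
#' Takes baseline and follow-up PHQ-9 (0-27) and GAD-7 (0-21) scores and
#' derives the change scores and the clinically-alarming flags (an increase
#' of at least 5 points between waves). Range violations are errors.
#'
#' @param survey A data frame with `participant_id`, `phq9_before`,
#'   `phq9_after`, `gad7_before`, `gad7_after`, and optionally demographic
#'   columns (`gender`, `year`, `citizen`).
#' @return A tibble with added `delta_phq9`, `delta_gad7`, `alarming_phq9`,
#'   `alarming_gad7` columns.
#' @examples
#' survey_panel(tibble::tibble(
#'   participant_id = "p1", phq9_before = 4, phq9_after = 10,
#'   gad7_before = 3, gad7_after = 5
#' ))
#' @export
survey_panel <- function(survey) {
  survey <- as_tibble(survey)
  need <- c("participant_id", "phq9_before", "phq9_after", "gad7_before", "gad7_after")
  miss <- setdiff(need, names(survey))
  if (length(miss)) abort(paste("survey missing columns:", paste(miss, collapse = ", ")))
  chk <- function(x, lo, hi, nm) {
    x <- as.integer(x)
    if (anyNA(x) || any(x < lo | x > hi)) {
      abort(sprintf("`%s` must be integers in [%d, %d]", nm, lo, hi))
    }
    x
  }
  survey |>
    mutate(
      phq9_before = chk(.data$phq9_before, 0, 27, "phq9_before"),
      phq9_after = chk(.data$phq9_after, 0, 27, "phq9_after"),
      gad7_before = chk(.data$gad7_before, 0, 21, "gad7_before"),
      gad7_after = chk(.data$gad7_after, 0, 21, "gad7_after"),
      delta_phq9 = .data$phq9_after - .data$phq9_before,
      delta_gad7 = .data$gad7_after - .data$gad7_before,
      alarming_phq9 = .data$delta_phq9 >= 5,
      alarming_gad7 = .data$delta_gad7 >= 5
    )
}

#' Read and write the survey CSV table
#'
#' CSV with header `participant_id, phq9_before, phq9_after, gad7_before,
#' gad7_after, gender, year, citizen`; the derived delta and alarming columns
#' are recomputed on read.
#'
#' @param path File path.
#' @return `read_survey()` returns a validated [survey_panel()] tibble.
#' @export
read_survey <- function(path) {
  survey_panel(as_tibble(utils::read.csv(path)))
}

#' @rdname read_survey
#' @param survey A survey tibble.
#' @export
write_survey <- function(survey, path) {
  survey <- survey_panel(survey)
  keep <- intersect(
    c("participant_id", "phq9_before", "phq9_after", "gad7_before", "gad7_after",
      "gender", "year", "citizen"),
    names(survey)
  )
  utils::write.csv(survey[keep], path, row.names = FALSE)
  invisible(path)
}
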