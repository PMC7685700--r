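#' Extract the behavioral shift feature table
#'
#' Runs the full before/after feature battery for every participant and
#' returns one tidy table, one row per (participant, feature, parameter):
#'
#' * `hourly_change` — per local hour 0-23, relative change of the per-day
#'   activity rate between windows;
#' * `last_seen_shift` — shift (hours) of the median last nightly activity,
#'   for each cutoff hour 0-5;
#' * `sei_change` — relative change in short-event-interval counts, per
#'   platform, at the pooled mixture thresholds;
#' * `lexicon_search` / `lexicon_video` — per-dimension relative change of
#'   lexicon word counts in the search-query and video-title/virtual-query
#'   text streams, plus the summary-score hooks (reported as a score
#'   difference, since composite scores can be negative);
#' * `category_change` — relative change of rule-annotated category volumes
#'   (`adult` restricted to the search platform, by convention).
#'
#' Session thresholds are fitted once per platform by pooling all
#' within-window gaps across the cohort (one tau per platform), unless
#' supplied.
#'
#' @param events Event tibble for the whole cohort (all windows).
#' @param windows An [analysis_windows()] object.
#' @param lex A [lexicon()]; defaults to the bundled synthetic lexicon.
#' @param rules [category_rules()]; defaults to the bundled demo rules.
#' @param taus Named numeric `c(google_search = , youtube = )` thresholds in
#'   seconds, or `NULL` to fit them from the data.
#' @param cutoff_hours Last-seen cutoff hours to sweep.
#' @param zero_policy Zero-baseline policy for all relative changes.
#' @param summary_weights Named list of summary-score weight vectors applied
#'   as `lexicon_search`/`lexicon_video` hook features (first entry on the
#'   search stream, second on the video stream by default layout of
#'   [default_summary_weights()]).
#' @param night_anchor Local hour at which nights begin.
#' @param quiet Suppress progress messages.
#' @return A tidy tibble `(participant_id, feature_name, parameter, value)`
#'   of class `shift_features`, with the fitted `taus` as an attribute.
#' @export
extract_features <- function(events, windows,
                             lex = phenoshift_lexicon(),
                             rules = default_category_rules(),
                             taus = NULL,
                             cutoff_hours = 0:5,
                             zero_policy = c("strict", "pseudo"),
                             summary_weights = default_summary_weights(),
                             night_anchor = 18,
                             quiet = FALSE) {
  zero_policy <- match.arg(zero_policy)
  seg <- segment_events(events, windows, quiet = TRUE)
  before <- seg[seg$window == "before", ]
  after <- seg[seg$window == "after", ]

  if (is.null(taus)) {
    taus <- vapply(PLATFORMS, function(pf) {
      gaps <- c(platform_gaps(before, pf), platform_gaps(after, pf))
      fit_gap_mixture(gaps, platform = pf)$tau_seconds
    }, numeric(1))
    if (!quiet) {
      inform(sprintf("fitted session thresholds: %s",
                     paste(sprintf("%s = %.1f s", names(taus), taus), collapse = ", ")))
    }
  }
  taus <- taus[PLATFORMS]

  days_b <- window_days(windows, "before")
  days_a <- window_days(windows, "after")
  tz <- windows$tz

  per_participant <- function(id) {
    b <- before[before$participant_id == id, ]
    a <- after[after$participant_id == id, ]

    hb <- hourly_histogram(b, days_b, tz = tz, normalize = TRUE)
    ha <- hourly_histogram(a, days_a, tz = tz, normalize = TRUE)
    hc <- hourly_relative_change(hb, ha, zero_policy)
    rows <- list(tibble(
      feature_name = "hourly_change", parameter = as.character(hc$hour),
      value = hc$change_percent
    ))

    rows <- c(rows, list(tibble(
      feature_name = "last_seen_shift",
      parameter = as.character(cutoff_hours),
      value = unname(vapply(cutoff_hours, function(Tcut) {
        last_seen_shift(b, a, cutoff_hour = Tcut, night_anchor = night_anchor, tz = tz)
      }, numeric(1)))
    )))

    rows <- c(rows, list(tibble(
      feature_name = "sei_change",
      parameter = PLATFORMS,
      value = unname(vapply(PLATFORMS, function(pf) {
        sei_relative_change(b, a, platform = pf, tau = taus[[pf]], zero_policy) |>
          dplyr::pull("change_percent")
      }, numeric(1)))
    )))

    search_b <- b$text[b$platform == "google_search" & nzchar(b$text)]
    search_a <- a$text[a$platform == "google_search" & nzchar(a$text)]
    video_b <- b$text[b$platform == "youtube" & nzchar(b$text)]
    video_a <- a$text[a$platform == "youtube" & nzchar(a$text)]

    lex_rows <- function(bt, at, stream) {
      lc <- lexicon_relative_change(bt, at, lex, zero_policy)
      tibble(feature_name = stream, parameter = lc$dimension, value = lc$change_percent)
    }
    rows <- c(rows, list(lex_rows(search_b, search_a, "lexicon_search"),
                         lex_rows(video_b, video_a, "lexicon_video")))

    hook <- function(texts_b, texts_a, w) {
      lexicon_summary_score(texts_a, lex, w) - lexicon_summary_score(texts_b, lex, w)
    }
    rows <- c(rows, list(tibble(
      feature_name = c("lexicon_search", "lexicon_video"),
      parameter = names(summary_weights)[1:2],
      value = c(
        hook(search_b, search_a, summary_weights[[1]]),
        hook(video_b, video_a, summary_weights[[2]])
      )
    )))

    cat_events <- function(ev) {
      list(all = ev, google = ev[ev$platform == "google_search", ])
    }
    cb <- cat_events(b); ca <- cat_events(a)
    cat_val <- function(category) {
      src_b <- if (category == "adult") cb$google else cb$all
      src_a <- if (category == "adult") ca$google else ca$all
      cc <- category_relative_change(src_b, src_a, rules, zero_policy)
      cc$change_percent[cc$category == category]
    }
    rows <- c(rows, list(tibble(
      feature_name = "category_change", parameter = names(rules),
      value = unname(vapply(names(rules), cat_val, numeric(1)))
    )))

    bind_rows(rows) |> mutate(participant_id = id, .before = 1)
  }

  ids <- sort(unique(seg$participant_id))
  out <- bind_rows(lapply(ids, per_participant))
  structure(out, class = c("shift_features", class(out)), taus = taus)
}

#' Pivot the tidy feature table to one row per participant
#'
#' Column names are `feature_name` and `parameter` joined with `_`, e.g.
#' `hourly_change_3` or `lexicon_video_anxiety`.
#'
#' @param features A tidy feature table from [extract_features()].
#' @return A wide tibble keyed by `participant_id`.
#' @export
features_wide <- function(features) {
  features |>
    mutate(name = paste(.data$feature_name, .data$parameter, sep = "_")) |>
    select("participant_id", "name", "value") |>
    tidyr::pivot_wider(names_from = "name", values_from = "value")
}

#' Write the tidy feature CSV
#'
#' Layout: `participant_id, feature_name, parameter, value`.
#'
#' @param features Tidy feature table.
#' @param path Output path.
#' @export
write_features <- function(features, path) {
  utils::write.csv(
    features[c("participant_id", "feature_name", "parameter", "value")],
    path, row.names = FALSE
  )
  invisible(path)
}
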