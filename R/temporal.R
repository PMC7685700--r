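#' Hourly activity profile
#'
#' Tallies a participant's events into 24 local-hour bins, optionally
#' normalized to events per day so that windows of unequal length (for
#' example 60 vs 64 days) are comparable. Per-day normalization is the
#' default for analysis; `normalize = FALSE` gives the raw cumulative counts.
#'
#' @param events Event tibble (typically one participant, one window).
#' @param window_days Length of the window in days (used for normalization).
#' @param tz Local timezone for the hour-of-day computation.
#' @param normalize Divide counts by `window_days`?
#' @return A tibble of class `hourly_profile` with columns `hour` (0-23) and
#'   `value`, plus `window_days` and `normalized` attributes. Raw bin values
#'   always sum to the number of events.
#' @examples
#' ev <- tibble::tibble(
#'   participant_id = "p1",
#'   timestamp = as.POSIXct(c("2020-01-02 02:10:00", "2020-01-02 02:59:00",
#'                            "2020-01-03 14:00:00"), tz = "America/New_York"),
#'   platform = "google_search", action = "search_query", text = "", url = ""
#' )
#' hourly_histogram(ev, window_days = 60, normalize = FALSE)
#' @export
hourly_histogram <- function(events, window_days, tz = "America/New_York",
                             normalize = TRUE) {
  stopifnot(window_days > 0)
  h <- if (nrow(events) == 0) integer(0) else hour(with_tz(events$timestamp, tz))
  counts <- tabulate(h + 1L, nbins = 24L)
  out <- tibble(
    hour = 0:23,
    value = if (normalize) counts / window_days else as.numeric(counts)
  )
  structure(out,
    class = c("hourly_profile", class(out)),
    window_days = window_days, normalized = normalize
  )
}

#' Per-hour relative change between two hourly profiles
#'
#' Applies the package's relative-change rule bin by bin. Both profiles must
#' share the same normalization mode. Under the `"pseudo"` zero policy the
#' event-equivalent is one event (or one event per day of the *before*
#' window, if the profiles are normalized).
#'
#' @param before,after [hourly_histogram()] profiles.
#' @inheritParams relative_change
#' @return A tibble of class `hourly_change` with columns `hour` and
#'   `change_percent` (`NA` where the baseline is zero under `"strict"`).
#' @export
hourly_relative_change <- function(before, after, zero_policy = c("strict", "pseudo")) {
  zero_policy <- match.arg(zero_policy)
  stopifnot(inherits(before, "hourly_profile"), inherits(after, "hourly_profile"))
  if (!identical(attr(before, "normalized"), attr(after, "normalized"))) {
    abort("profiles have mismatched normalization; recompute with the same mode")
  }
  unit <- if (attr(before, "normalized")) 1 / attr(before, "window_days") else 1
  out <- tibble(
    hour = before$hour,
    change_percent = relative_change(before$value, after$value, zero_policy, pseudo_unit = unit)
  )
  structure(out,
    class = c("hourly_change", class(out)),
    zero_policy = zero_policy
  )
}

#' Last nightly activity before a cutoff hour
#'
#' A bedtime proxy: for each night, the time of the final event between the
#' evening anchor (default 18:00 local) and a late-night/early-morning cutoff
#' `T` on the next day. Times are encoded as continuous hours since midnight
#' of the night's starting day, so 1:30 AM the next morning encodes as 25.5;
#' this keeps medians meaningful across the midnight boundary. Nights with no
#' qualifying event contribute nothing.
#'
#' @param events Event tibble (one participant, one window), any platform.
#' @param cutoff_hour Integer cutoff `T` in 0-5: the night window is
#'   `[anchor, 24 + T)` hours; `T = 0` ends at midnight.
#' @param night_anchor Local hour at which a "night" begins (default 18).
#' @param tz Local timezone.
#' @return A tibble with `night` (Date of the evening the night belongs to)
#'   and `last_seen` (encoded hours), one row per night with activity.
#' @export
last_seen_times <- function(events, cutoff_hour = 4, night_anchor = 18,
                            tz = "America/New_York") {
  if (!cutoff_hour %in% 0:5) abort("`cutoff_hour` must be an integer in 0..5")
  if (night_anchor <= 12 + cutoff_hour) abort("night window is empty or inverted")
  if (nrow(events) == 0) {
    return(tibble(night = as.Date(character()), last_seen = numeric()))
  }
  local <- with_tz(events$timestamp, tz)
  hrs <- hour(local) + minute(local) / 60 + second(local) / 3600
  day <- as_date(local)
  evening <- hrs >= night_anchor
  morning <- hrs < cutoff_hour
  keep <- evening | morning
  if (!any(keep)) {
    return(tibble(night = as.Date(character()), last_seen = numeric()))
  }
  tibble(
    night = dplyr::if_else(evening[keep], day[keep], day[keep] - 1L),
    encoded = hrs[keep] + dplyr::if_else(evening[keep], 0, 24)
  ) |>
    group_by(.data$night) |>
    summarise(last_seen = max(.data$encoded), .groups = "drop")
}

#' Shift in the median last-seen time between windows
#'
#' The median of the per-night last-seen encodings is taken in each window
#' and differenced (`after - before`), in hours. A positive value means the
#' typical final nightly activity moved later after the boundary; for
#' example, +1.5 means a 1.5-hour delay.
#'
#' @param before_events,after_events Event tibbles for the two windows.
#' @inheritParams last_seen_times
#' @return A single numeric shift in hours, or `NA` (with a message) when a
#'   window has no qualifying night.
#' @export
last_seen_shift <- function(before_events, after_events, cutoff_hour = 4,
                            night_anchor = 18, tz = "America/New_York") {
  b <- last_seen_times(before_events, cutoff_hour, night_anchor, tz)
  a <- last_seen_times(after_events, cutoff_hour, night_anchor, tz)
  if (nrow(b) == 0 || nrow(a) == 0) {
    inform("last_seen_shift: no qualifying nights in at least one window; returning NA")
    return(NA_real_)
  }
  median(a$last_seen) - median(b$last_seen)
}

# inter-event gaps (seconds) between adjacent same-platform events,
# computed within participant; events are assumed to lie in one window so
# no gap spans the excluded buffer
platform_gaps <- function(events, platform) {
  ev <- events[events$platform == platform, , drop = FALSE]
  if (nrow(ev) < 2) return(numeric(0))
  ev <- ev[order(ev$participant_id, ev$timestamp), ]
  gaps <- as.numeric(diff(ev$timestamp), units = "secs")
  same <- ev$participant_id[-1] == ev$participant_id[-nrow(ev)]
  gaps[same]
}

#' Count short event intervals
#'
#' A short event interval (SEI) is a gap below the platform's session
#' threshold `tau` between two adjacent events on the same platform,
#' indicating consecutive consumption within one session. Gaps are computed
#' per participant within one analysis window; gaps spanning windows are
#' never formed.
#'
#' @param events Event tibble for one window (one or more participants).
#' @param platform `"google_search"` or `"youtube"`.
#' @param tau Session threshold in seconds (see [fit_gap_mixture()]).
#' @return Integer count of gaps strictly below `tau`.
#' @export
count_short_intervals <- function(events, platform = "youtube", tau) {
  stopifnot(tau > 0)
  platform <- match.arg(platform, PLATFORMS)
  sum(platform_gaps(events, platform) < tau)
}

#' Relative change in short-interval counts
#'
#' Counts SEIs in the before and after windows and applies the package's
#' relative-change rule, per participant.
#'
#' @param before_events,after_events Event tibbles for the two windows.
#' @inheritParams count_short_intervals
#' @inheritParams relative_change
#' @return A tibble with `participant_id`, `sei_before`, `sei_after`,
#'   `change_percent`.
#' @export
sei_relative_change <- function(before_events, after_events, platform = "youtube",
                                tau, zero_policy = c("strict", "pseudo")) {
  zero_policy <- match.arg(zero_policy)
  count_by <- function(ev) {
    ids <- unique(ev$participant_id)
    tibble(
      participant_id = ids,
      n = unname(vapply(ids, function(id) {
        count_short_intervals(ev[ev$participant_id == id, ], platform, tau)
      }, numeric(1)))
    )
  }
  all_ids <- union(unique(before_events$participant_id), unique(after_events$participant_id))
  tibble(participant_id = all_ids) |>
    left_join(count_by(before_events) |> rename(sei_before = "n"), by = "participant_id") |>
    left_join(count_by(after_events) |> rename(sei_after = "n"), by = "participant_id") |>
    mutate(
      sei_before = tidyr::replace_na(.data$sei_before, 0),
      sei_after = tidyr::replace_na(.data$sei_after, 0),
      change_percent = relative_change(.data$sei_before, .data$sei_after, zero_policy)
    )
}
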