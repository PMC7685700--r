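#' Analysis windows around the event boundary
#'
#' Defines the three half-open calendar intervals used throughout the
#' analysis: a `before` window, an `excluded` buffer around the boundary
#' (dropped so that acute, transitional behavior does not contaminate either
#' side), and an `after` window. All three are interpreted in one local
#' timezone; every temporal feature in the package is computed on the local
#' clock, since notions such as "3 AM" or "late night" only make sense in the
#' participant's own time.
#'
#' The defaults are the 2020 pre/post-lockdown windows: January 1 to
#' March 1 (before), March 1 to March 29 (excluded), and March 29 to
#' June 1 (after), all half-open `[start, end)`.
#'
#' @param before,excluded,after Length-2 character or Date vectors
#'   `c(start, end)`; each interval is half-open `[start, end)`.
#' @param tz Olson timezone name used for all local-time computations.
#' @return An object of class `analysis_windows`.
#' @examples
#' w <- analysis_windows()
#' window_days(w, "before")
#' @export
analysis_windows <- function(before = c("2020-01-01", "2020-03-01"),
                             excluded = c("2020-03-01", "2020-03-29"),
                             after = c("2020-03-29", "2020-06-01"),
                             tz = "America/New_York") {
  parse_iv <- function(x, name) {
    if (length(x) != 2) abort(paste0("`", name, "` must be c(start, end)"))
    d <- as_date(x)
    if (any(is.na(d))) abort(paste0("`", name, "` has unparseable dates"))
    if (d[1] >= d[2]) abort(paste0("`", name, "` must have start < end"))
    d
  }
  w <- structure(
    list(
      before = parse_iv(before, "before"),
      excluded = parse_iv(excluded, "excluded"),
      after = parse_iv(after, "after"),
      tz = tz
    ),
    class = "analysis_windows"
  )
  if (!(w$before[2] <= w$excluded[1] && w$excluded[2] <= w$after[1])) {
    abort("windows must be chronologically ordered and pairwise disjoint")
  }
  w
}

#' @export
print.analysis_windows <- function(x, ...) {
  cat("<analysis_windows> tz =", x$tz, "\n")
  for (nm in c("before", "excluded", "after")) {
    cat(sprintf("  %-8s [%s, %s)  %d days\n", nm,
                format(x[[nm]][1]), format(x[[nm]][2]),
                as.integer(diff(x[[nm]]))))
  }
  invisible(x)
}

#' @rdname analysis_windows
#' @param windows An `analysis_windows` object.
#' @param which One of `"before"`, `"excluded"`, `"after"`.
#' @export
window_days <- function(windows, which = "before") {
  stopifnot(inherits(windows, "analysis_windows"))
  as.numeric(diff(windows[[match.arg(which, c("before", "excluded", "after"))]]))
}

# window boundaries as local POSIXct instants
window_bounds <- function(windows, which) {
  iv <- windows[[which]]
  as.POSIXct(paste(iv, "00:00:00"), tz = windows$tz)
}

# midpoint date-time of a window (used as the x-coordinate for seasonal slopes)
window_midpoint <- function(windows, which) {
  b <- window_bounds(windows, which)
  b[1] + as.numeric(difftime(b[2], b[1], units = "secs")) / 2
}

#' Shift analysis windows by whole years
#'
#' Convenience for seasonal-control analyses that replay the same calendar
#' windows in an earlier year (for example, the 2019 counterpart of the 2020
#' windows).
#'
#' @param windows An `analysis_windows` object.
#' @param years Integer number of years to add (negative to go back).
#' @return An `analysis_windows` object.
#' @export
shift_windows_years <- function(windows, years = -1) {
  stopifnot(inherits(windows, "analysis_windows"))
  bump <- function(iv) iv + lubridate::years(years)
  analysis_windows(
    before = bump(windows$before), excluded = bump(windows$excluded),
    after = bump(windows$after), tz = windows$tz
  )
}

#' Assign events to analysis windows
#'
#' Labels every event with the window containing its local-time instant.
#' Assignment uses half-open `[start, end)` intervals so each instant belongs
#' to exactly one bucket; events falling outside all three windows are labelled
#' `"out_of_range"` and are retained in the returned table but excluded from
#' every downstream feature.
#'
#' @param events A tibble of activity events with at least `timestamp`
#'   (POSIXct) and `participant_id`.
#' @param windows An [analysis_windows()] object.
#' @param quiet Suppress the assignment summary message.
#' @return The events tibble with an added `window` factor column, sorted by
#'   participant and time.
#' @examples
#' ev <- tibble::tibble(
#'   participant_id = "p1",
#'   timestamp = as.POSIXct("2020-03-01 00:00:00", tz = "America/New_York"),
#'   platform = "google_search", action = "search_query", text = "", url = ""
#' )
#' segment_events(ev, analysis_windows())$window  # "excluded": half-open cut
#' @export
segment_events <- function(events, windows, quiet = FALSE) {
  stopifnot(inherits(windows, "analysis_windows"))
  events <- validate_events(events)
  local <- with_tz(events$timestamp, windows$tz)
  lab <- rep("out_of_range", nrow(events))
  for (nm in c("before", "excluded", "after")) {
    b <- window_bounds(windows, nm)
    lab[local >= b[1] & local < b[2]] <- nm
  }
  out <- events |>
    mutate(window = factor(lab, levels = c("before", "excluded", "after", "out_of_range"))) |>
    arrange(.data$participant_id, .data$timestamp)
  if (!quiet) {
    tab <- table(out$window)
    inform(sprintf(
      "segment_events: %d events -> before %d, excluded %d, after %d, out_of_range %d",
      nrow(out), tab[["before"]], tab[["excluded"]], tab[["after"]], tab[["out_of_range"]]
    ))
  }
  out
}

#' Read analysis windows from a YAML config file
#'
#' The file holds ISO dates under `before`, `excluded`, `after` (each a list
#' with `start` and `end`) and a `tz` entry.
#'
#' @param path Path to a YAML file.
#' @return An [analysis_windows()] object.
#' @export
read_windows_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  analysis_windows(
    before = c(cfg$before$start, cfg$before$end),
    excluded = c(cfg$excluded$start, cfg$excluded$end),
    after = c(cfg$after$start, cfg$after$end),
    tz = cfg$tz %||% "America/New_York"
  )
}

#' @rdname read_windows_config
#' @param windows An `analysis_windows` object to serialize.
#' @export
write_windows_config <- function(windows, path) {
  stopifnot(inherits(windows, "analysis_windows"))
  yaml::write_yaml(list(
    before = list(start = format(windows$before[1]), end = format(windows$before[2])),
    excluded = list(start = format(windows$excluded[1]), end = format(windows$excluded[2])),
    after = list(start = format(windows$after[1]), end = format(windows$after[2])),
    tz = windows$tz
  ), path)
  invisible(path)
}
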