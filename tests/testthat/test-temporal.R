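tz <- "America/New_York"

test_that("hourly histogram bins by local hour and conserves the event count", {
  ev <- make_events(c("2020-01-02 02:10:00", "2020-01-02 02:59:00",
                      "2020-01-03 14:00:00"))
  hp <- hourly_histogram(ev, window_days = 60, normalize = FALSE)
  expect_equal(hp$value[hp$hour == 2], 2)
  expect_equal(hp$value[hp$hour == 14], 1)
  expect_equal(sum(hp$value), 3)

  ev1 <- make_events(rep("2020-01-02 07:30:00", 5))
  hp1 <- hourly_histogram(ev1, window_days = 1, normalize = FALSE)
  expect_equal(hp1$value[hp1$hour == 7], 5)
  expect_equal(sum(hp1$value != 0), 1)

  empty <- hourly_histogram(ev[0, ], window_days = 10, normalize = FALSE)
  expect_equal(sum(empty$value), 0)
})

test_that("hourly histogram matches a brute-force per-hour tally", {
  for (seed in 1:20) {
    ev <- random_events(250, seed)
    hp <- hourly_histogram(ev, window_days = 170, tz = tz, normalize = FALSE)
    expect_equal(hp$value, oracle_hourly(ev, tz))
  }
})

test_that("normalization divides by window length and modes cannot be mixed", {
  ev <- make_events(rep("2020-01-02 10:00:00", 6))
  raw <- hourly_histogram(ev, window_days = 3, normalize = FALSE)
  per_day <- hourly_histogram(ev, window_days = 3, normalize = TRUE)
  expect_equal(per_day$value, raw$value / 3)
  expect_error(hourly_relative_change(raw, per_day), "normalization")
})

test_that("per-hour relative change follows the shared rule and policies", {
  mk <- function(vals, days = 1, norm = FALSE) {
    hp <- hourly_histogram(make_events(character(0)), window_days = days,
                           normalize = norm)
    hp$value <- vals
    hp
  }
  b <- mk(c(100, 0, rep(1, 22)))
  a <- mk(c(150, 7, rep(1, 22)))
  strict <- hourly_relative_change(b, a, "strict")
  expect_equal(strict$change_percent[1], 50)
  expect_true(is.na(strict$change_percent[2]))
  pseudo <- hourly_relative_change(b, a, "pseudo")
  expect_equal(pseudo$change_percent[2], 700)
  same <- hourly_relative_change(b, b, "strict")
  expect_equal(same$change_percent[-2], rep(0, 23))
})

test_that("last-seen encoding spans midnight on a continuous scale", {
  ev <- make_events(c("2020-01-05 23:30:00", "2020-01-06 01:10:00"))
  ls <- last_seen_times(ev, cutoff_hour = 2, tz = tz)
  expect_equal(nrow(ls), 1)
  expect_equal(ls$last_seen, 25 + 10 / 60, tolerance = 1e-9)

  ev0 <- make_events("2020-01-05 19:00:00")
  ls0 <- last_seen_times(ev0, cutoff_hour = 0, tz = tz)
  expect_equal(ls0$last_seen, 19)

  # an event after the cutoff does not qualify
  ev2 <- make_events("2020-01-06 03:30:00")
  expect_equal(nrow(last_seen_times(ev2, cutoff_hour = 2, tz = tz)), 0)
  expect_error(last_seen_times(ev0, cutoff_hour = 7), "0..5")
})

test_that("last-seen times match the brute-force night scan", {
  for (seed in 1:20) {
    ev <- random_events(150, seed)
    for (Tcut in c(0, 2, 5)) {
      got <- sort(last_seen_times(ev, cutoff_hour = Tcut, tz = tz)$last_seen)
      expect_equal(got, oracle_last_seen(ev, Tcut, 18, tz), tolerance = 1e-9)
    }
  }
})

test_that("median last-seen shift does median arithmetic and sign convention", {
  mk_nights <- function(hours_list, start_day) {
    # one event per night at the requested encoded hour
    times <- mapply(function(h, d) {
      day <- as.Date(start_day) + d
      as.POSIXct(paste(day, "00:00:00"), tz = tz) + h * 3600
    }, hours_list, seq_along(hours_list) - 1)
    make_events(as.POSIXct(times, origin = "1970-01-01", tz = tz))
  }
  before <- mk_nights(c(24.5, 25.0, 24.8), "2020-01-05")
  after <- mk_nights(c(26.0, 26.4), "2020-02-05")
  expect_equal(
    last_seen_shift(before, after, cutoff_hour = 4, tz = tz),
    26.2 - 24.8, tolerance = 1e-9
  )
  expect_equal(last_seen_shift(before, before, cutoff_hour = 4, tz = tz), 0)
  expect_message(
    out <- last_seen_shift(before[0, ], after, cutoff_hour = 4, tz = tz),
    "no qualifying nights"
  )
  expect_true(is.na(out))
})

test_that("a pure time translation of the night stream shifts the median exactly", {
  # events kept between 19:00 and 01:00 so a +0.9 h translation stays inside
  # every night window at the 5 AM cutoff; the shift must then be exact
  withr::with_seed(21, {
    nights <- as.Date("2020-01-05") + 0:29
    hrs <- runif(90, 19, 25)
    days <- sample(nights, 90, replace = TRUE)
    ev <- make_events(as.POSIXct(paste(days, "00:00:00"), tz = tz) + hrs * 3600)
  })
  shifted <- ev
  shifted$timestamp <- shifted$timestamp + 0.9 * 3600
  expect_equal(last_seen_shift(ev, shifted, cutoff_hour = 5, tz = tz), 0.9,
               tolerance = 1e-9)
})

test_that("short-interval counting is an adjacent same-platform pair count", {
  t0 <- as.POSIXct("2020-01-05 10:00:00", tz = tz)
  ev <- make_events(t0 + c(0, 60, 4000), platform = "youtube")
  expect_equal(count_short_intervals(ev, "youtube", tau = 3600), 1)
  expect_equal(count_short_intervals(ev[1, ], "youtube", tau = 3600), 0)
  # platforms do not interleave
  mixed <- dplyr::bind_rows(
    make_events(t0 + c(0, 7000), platform = "youtube"),
    make_events(t0 + 3500, platform = "google_search")
  )
  expect_equal(count_short_intervals(mixed, "youtube", tau = 3600), 0)
  expect_equal(count_short_intervals(mixed, "google_search", tau = 3600), 0)
})

test_that("short-interval counts match the quadratic brute force", {
  for (seed in 1:20) {
    ev <- random_events(120, seed)
    for (tau in c(600, 3600, 7200)) {
      expect_equal(count_short_intervals(ev, "youtube", tau),
                   oracle_sei(ev, "youtube", tau))
      expect_equal(count_short_intervals(ev, "google_search", tau),
                   oracle_sei(ev, "google_search", tau))
    }
  }
})

test_that("SEI relative change composes counting with the shared rule", {
  t0 <- as.POSIXct("2020-01-05 10:00:00", tz = tz)
  before <- make_events(t0 + seq(0, by = 30, length.out = 101), platform = "youtube")
  after <- make_events(t0 + 40 * 86400 + seq(0, by = 30, length.out = 151),
                       platform = "youtube")
  out <- sei_relative_change(before, after, "youtube", tau = 300)
  expect_equal(out$sei_before, 100)
  expect_equal(out$sei_after, 150)
  expect_equal(out$change_percent, 50)
  same <- sei_relative_change(before, before, "youtube", tau = 300)
  expect_equal(same$change_percent, 0)
})
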