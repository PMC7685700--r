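# ---- small constructors ----------------------------------------------------

make_events <- function(times, platform = "google_search", action = NULL,
                        text = "", url = "", id = "p1",
                        tz = "America/New_York") {
  if (is.character(times)) times <- as.POSIXct(times, tz = tz)
  if (is.null(action)) {
    action <- ifelse(platform == "youtube", "video_watch", "search_query")
  }
  tibble::tibble(
    participant_id = id, timestamp = times,
    platform = platform, action = action, text = text, url = url
  )
}

short_windows <- function() {
  analysis_windows(
    before = c("2020-01-01", "2020-01-21"),
    excluded = c("2020-01-21", "2020-01-23"),
    after = c("2020-01-23", "2020-02-12")
  )
}

# uniformly random events across the three windows plus some out-of-range
random_events <- function(n, seed, id = "p1", tz = "America/New_York") {
  withr::with_seed(seed, {
    t0 <- as.POSIXct("2019-12-25 00:00:00", tz = tz)
    make_events(
      t0 + floor(runif(n, 0, 170 * 86400)), # schema is second-precise
      platform = sample(c("google_search", "youtube"), n, TRUE),
      action = NULL, id = id, tz = tz
    ) |>
      dplyr::mutate(action = ifelse(platform == "youtube", "video_watch", "search_query")) |>
      dplyr::arrange(timestamp)
  })
}

tiny_cohort_config <- function(n = 8, seed = 11, daily_rate = 25, ...) {
  cohort_config(
    n_participants = n, seed = seed,
    profile = behavior_profile(daily_rate = daily_rate),
    ...
  )
}

# ---- independent brute-force oracles ---------------------------------------

# per-hour tally by explicit loop over events
oracle_hourly <- function(events, tz) {
  counts <- numeric(24)
  for (i in seq_len(nrow(events))) {
    h <- as.integer(format(lubridate::with_tz(events$timestamp[i], tz), "%H"))
    counts[h + 1] <- counts[h + 1] + 1
  }
  counts
}

# O(n * nights) scan for the last qualifying event of each night, working
# entirely on wall-clock components parsed from formatted strings (the
# bedtime semantics are local clock time, also across DST transitions)
oracle_last_seen <- function(events, cutoff_hour, night_anchor, tz) {
  if (nrow(events) == 0) return(numeric(0))
  local <- lubridate::with_tz(events$timestamp, tz)
  wall_day <- as.Date(format(local, "%Y-%m-%d", tz = tz))
  wall_hr <- as.numeric(format(local, "%H", tz = tz)) +
    as.numeric(format(local, "%M", tz = tz)) / 60 +
    as.numeric(format(local, "%S", tz = tz)) / 3600
  dates <- seq(min(wall_day) - 1, max(wall_day), by = "day")
  out <- c()
  for (d in as.list(dates)) {
    enc <- c(
      wall_hr[wall_day == d & wall_hr >= night_anchor],
      wall_hr[wall_day == d + 1 & wall_hr < cutoff_hour] + 24
    )
    if (length(enc)) out <- c(out, max(enc))
  }
  sort(out)
}

# quadratic-time short-interval pair count
oracle_sei <- function(events, platform, tau) {
  ev <- events[events$platform == platform, ]
  ev <- ev[order(ev$participant_id, ev$timestamp), ]
  n <- 0L
  if (nrow(ev) < 2) return(n)
  for (i in 2:nrow(ev)) {
    if (ev$participant_id[i] == ev$participant_id[i - 1]) {
      gap <- as.numeric(difftime(ev$timestamp[i], ev$timestamp[i - 1], units = "secs"))
      if (gap < tau) n <- n + 1L
    }
  }
  n
}

# regex-based re-tokenization and dimension counting
oracle_lexicon <- function(texts, lex) {
  tokens <- unlist(regmatches(tolower(texts), gregexpr("[a-z0-9]+", tolower(texts))))
  vapply(lex$dimensions, function(patterns) {
    rx <- paste0("^(", paste(vapply(patterns, function(p) {
      if (endsWith(p, "*")) paste0(gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", sub("\\*$", "", p)), ".*")
      else gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", p)
    }, character(1)), collapse = "|"), ")$")
    sum(grepl(rx, tokens))
  }, numeric(1))
}

# textbook covariance-formula Pearson r and its t-based p / Fisher CI
oracle_pearson <- function(x, y, conf = 0.95) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  z <- atanh(r)
  hw <- stats::qnorm(1 - (1 - conf) / 2) / sqrt(n - 3)
  list(r = r, p = p, ci = tanh(c(z - hw, z + hw)))
}

# paired t recomputed as a one-sample t on the differences, from scratch
oracle_paired_t <- function(a, b) {
  d <- b - a
  n <- length(d)
  tstat <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df = n - 1))
}

# closed-form leave-one-out mean squared error for OLS with intercept
# (PRESS residuals via the hat matrix; affine-invariant, so valid even
# though the implementation standardizes within folds)
oracle_loo_mse_ols <- function(X, y) {
  Z <- cbind(1, as.matrix(X))
  H <- Z %*% solve(crossprod(Z)) %*% t(Z)
  e <- y - H %*% y
  mean((e / (1 - diag(H)))^2)
}

# dense grid search for the equal-responsibility crossing of two known
# Gaussian components (same criterion, independent search strategy)
oracle_crossing <- function(mu, sigma, w) {
  grid <- seq(mu[1], mu[2], length.out = 200001)
  d <- log(w[1]) + stats::dnorm(grid, mu[1], sigma[1], log = TRUE) -
    log(w[2]) - stats::dnorm(grid, mu[2], sigma[2], log = TRUE)
  grid[which.min(abs(d))]
}
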