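# token pools the generator draws query/title text from; categories overlap
# deliberately with the bundled lexicon dimensions and category rules so that
# injected weight changes are recoverable by the semantic features
TOKEN_POOLS <- list(
  neutral = c("video", "music", "recipe", "weather", "tutorial", "lecture",
              "game", "movie", "calculus", "chemistry", "history", "maps",
              "translate", "review", "laptop", "phone", "shoes", "pizza",
              "guitar", "coffee", "bus", "schedule", "library", "dorm"),
  work = c("work", "working", "job", "jobs", "deadline", "homework",
           "internship", "resume", "career", "exams"),
  money = c("money", "cash", "rent", "loans", "salary", "budget", "tuition",
            "invest", "payment"),
  death = c("death", "dead", "dying", "funeral", "grief", "mortality", "died"),
  anxiety = c("anxiety", "anxious", "worry", "worried", "nervous", "panic",
              "stress", "overwhelmed", "i", "my"),
  sadness = c("sad", "sadness", "crying", "lonely", "hopeless", "depressed",
              "miserable", "i", "me"),
  friends = c("friend", "friends", "buddy", "roommate", "hangout", "party",
              "parties"),
  posemo = c("happy", "joy", "love", "great", "awesome", "fun", "relax"),
  negemo = c("hate", "angry", "awful", "terrible", "fear"),
  adult = c("porn", "xxx", "nsfw", "explicit"),
  news = c("news", "headlines", "election", "pandemic", "outbreak", "lockdown")
)

CATEGORY_DOMAINS <- list(
  adult = c("pornhub.com", "xvideos.com", "onlyfans.com"),
  news = c("cnn.com", "nytimes.com", "bbc.com", "reuters.com", "foxnews.com"),
  neutral = c("wikipedia.org", "weather.com", "stackexchange.com", "example.edu")
)

default_circadian_weights <- function() {
  # evening-heavy student profile: volume builds through the evening, peaks
  # near midnight, drops sharply after 1 AM and bottoms out before dawn; the
  # sharp night edge keeps the last-activity bedtime proxy well concentrated
  w <- c(7, 5.5, 1.2, 0.1, 0.05, 0.05, 0.2, 0.5, 1, 2, 3, 3.5,
         4, 4, 4, 4, 4.5, 4.5, 5, 5.5, 6, 6.5, 7.5, 7.5)
  w / sum(w)
}

default_category_weights <- function() {
  c(neutral = 0.56, work = 0.08, money = 0.04, friends = 0.06, posemo = 0.07,
    negemo = 0.03, anxiety = 0.03, sadness = 0.03, death = 0.01,
    adult = 0.03, news = 0.06)
}

#' Behavior profile for the synthetic generator
#'
#' Describes one simulated participant's online behavior: overall volume,
#' circadian placement, session structure (geometric session lengths with
#' lognormal within-session gaps), text category mixture and platform mix.
#' Fields with an `_after` suffix (and `bedtime_shift_hours` /
#' `category_weights_after`) apply only in the after window, so a profile
#' encodes both the pre-boundary behavior and the injected shift.
#'
#' The default volume of 85 events/day matches a cohort averaging roughly
#' 2400 searches plus 2900 watches per two-month window.
#'
#' @param daily_rate Expected events per day (> 0).
#' @param circadian_weights 24 nonnegative hour weights (normalized to sum
#'   to 1).
#' @param bedtime_shift_hours Hours by which the night-time (22:00-06:00)
#'   activity mass is rotated later in the after window.
#' @param session_length_p Geometric success probability in (0, 1]; mean
#'   session length is `1/p` events.
#' @param in_session_log10gap_mean,in_session_log10gap_sd Within-session gap
#'   distribution on log10 seconds.
#' @param between_session_log10gap_mean,between_session_log10gap_sd The
#'   between-session gap regime on log10 seconds; must lie above the
#'   in-session component. These parameterize the ground-truth session
#'   boundary recorded in the ledger.
#' @param category_weights,category_weights_after Named nonnegative weights
#'   over the generator's token-pool categories for the before and after
#'   windows (normalized).
#' @param platform_mix Fraction of sessions on the video platform, in
#'   `[0, 1]`.
#' @param daily_rate_after,session_length_p_after Optional after-window
#'   overrides (default: unchanged).
#' @return An object of class `behavior_profile`.
#' @export
behavior_profile <- function(daily_rate = 85,
                             circadian_weights = default_circadian_weights(),
                             bedtime_shift_hours = 0,
                             session_length_p = 0.3,
                             in_session_log10gap_mean = 1.3,
                             in_session_log10gap_sd = 0.35,
                             between_session_log10gap_mean = 3.6,
                             between_session_log10gap_sd = 0.55,
                             category_weights = default_category_weights(),
                             category_weights_after = category_weights,
                             platform_mix = 0.55,
                             daily_rate_after = NULL,
                             session_length_p_after = NULL) {
  if (daily_rate <= 0) abort("`daily_rate` must be positive")
  if (length(circadian_weights) != 24 || any(circadian_weights < 0) ||
      sum(circadian_weights) <= 0) {
    abort("`circadian_weights` must be 24 nonnegative values with positive sum")
  }
  if (session_length_p <= 0 || session_length_p > 1) {
    abort("`session_length_p` must be in (0, 1]")
  }
  if (in_session_log10gap_sd <= 0 || between_session_log10gap_sd <= 0) {
    abort("gap sds must be positive")
  }
  if (in_session_log10gap_mean >= between_session_log10gap_mean) {
    abort("in-session gaps must be shorter than between-session gaps")
  }
  if (platform_mix < 0 || platform_mix > 1) abort("`platform_mix` must be in [0, 1]")
  norm_w <- function(w) {
    if (is.null(names(w)) || any(w < 0) || sum(w) <= 0) {
      abort("category weights must be named and nonnegative with positive sum")
    }
    bad <- setdiff(names(w), names(TOKEN_POOLS))
    if (length(bad)) abort(paste("unknown token-pool categories:", paste(bad, collapse = ", ")))
    w / sum(w)
  }
  structure(list(
    daily_rate = daily_rate,
    circadian_weights = circadian_weights / sum(circadian_weights),
    bedtime_shift_hours = bedtime_shift_hours,
    session_length_p = session_length_p,
    in_session_log10gap_mean = in_session_log10gap_mean,
    in_session_log10gap_sd = in_session_log10gap_sd,
    between_session_log10gap_mean = between_session_log10gap_mean,
    between_session_log10gap_sd = between_session_log10gap_sd,
    category_weights = norm_w(category_weights),
    category_weights_after = norm_w(category_weights_after),
    platform_mix = platform_mix,
    daily_rate_after = daily_rate_after %||% daily_rate,
    session_length_p_after = session_length_p_after %||% session_length_p
  ), class = "behavior_profile")
}

# rotate the night-hour (22:00-06:00) circadian mass `delta` hours later,
# circularly within the 8-hour night arc; daytime mass stays in place
rotate_night_mass <- function(weights, delta) {
  if (delta == 0) return(weights)
  night_hours <- c(22, 23, 0:5)
  arc <- weights[night_hours + 1]
  k <- floor(delta) %% 8
  f <- delta - floor(delta)
  idx <- function(i) ((seq_len(8) - 1 - i) %% 8) + 1
  new_arc <- (1 - f) * arc[idx(k)] + f * arc[idx(k + 1)]
  out <- weights
  out[night_hours + 1] <- new_arc
  out
}

# ground-truth session boundary implied by a profile's gap regimes: the
# equal-responsibility crossing of the two configured components, with the
# in-session weight 1 - p (the expected fraction of within-session gaps)
true_gap_boundary_log10 <- function(profile, p = profile$session_length_p) {
  responsibility_crossing(
    mu = c(profile$in_session_log10gap_mean, profile$between_session_log10gap_mean),
    sigma = c(profile$in_session_log10gap_sd, profile$between_session_log10gap_sd),
    w = c(1 - p + 1e-6, p + 1e-6) / (1 + 2e-6)
  )
}

draw_texts <- function(n, weights, rng_pool = TOKEN_POOLS) {
  cats <- sample(names(weights), n, replace = TRUE, prob = weights)
  words <- character(n)
  for (cat in unique(cats)) {
    sel <- which(cats == cat)
    words[sel] <- sample(rng_pool[[cat]], length(sel), replace = TRUE)
  }
  n_fill <- sample(0:2, n, replace = TRUE, prob = c(0.3, 0.45, 0.25))
  f1 <- sample(rng_pool$neutral, n, replace = TRUE)
  f2 <- sample(rng_pool$neutral, n, replace = TRUE)
  txt <- words
  txt[n_fill >= 1] <- paste(txt[n_fill >= 1], f1[n_fill >= 1])
  txt[n_fill == 2] <- paste(txt[n_fill == 2], f2[n_fill == 2])
  list(text = txt, category = cats)
}

draw_url <- function(category, action) {
  n <- length(category)
  url <- character(n)
  yt <- action == "video_watch"
  url[yt] <- paste0("https://youtube.com/watch?v=v", seq_len(sum(yt)))
  visit <- action == "url_visit"
  if (any(visit)) {
    dom_cat <- ifelse(category %in% names(CATEGORY_DOMAINS), category, "neutral")
    doms <- vapply(dom_cat[visit], function(cc) sample(CATEGORY_DOMAINS[[cc]], 1),
                   character(1))
    url[visit] <- paste0("https://", doms, "/page")
  }
  url
}

# simulate one window of events for one participant; all randomness comes
# from the caller-established RNG state
simulate_window <- function(profile, windows, which, tz) {
  after <- which == "after"
  rate <- if (after) profile$daily_rate_after else profile$daily_rate
  p <- if (after) profile$session_length_p_after else profile$session_length_p
  cat_w <- if (after) profile$category_weights_after else profile$category_weights
  weights <- profile$circadian_weights
  n_days <- window_days(windows, which)
  if (n_days <= 0) abort("empty analysis window")
  n_events <- rpois(1, rate * n_days)
  empty <- tibble(
    timestamp = as.POSIXct(character(), tz = "UTC"), platform = character(),
    action = character(), text = character(), url = character()
  )
  if (n_events == 0) return(empty)

  sizes <- integer(0)
  while (sum(sizes) < n_events) {
    sizes <- c(sizes, 1L + rgeom(max(16L, ceiling(n_events * p)), p))
  }
  k <- which(cumsum(sizes) >= n_events)[1]
  sizes <- sizes[seq_len(k)]
  sizes[k] <- sizes[k] - (sum(sizes) - n_events)
  if (sizes[k] == 0L) {
    sizes <- sizes[-k]
    k <- k - 1L
  }

  dates <- windows[[which]][1] + sample(0:(n_days - 1), k, replace = TRUE)
  hours <- sample(0:23, k, replace = TRUE, prob = weights)
  start_sec <- hours * 3600 + runif(k) * 3600
  if (after && profile$bedtime_shift_hours != 0) {
    # rotate night-time (22:00-06:00) session starts later by the bedtime
    # shift, continuously and circularly within the 8-hour night arc; this
    # translates the whole night intensity, so the last-seen distribution
    # shifts by exactly the injected delta
    h_frac <- start_sec / 3600
    night <- h_frac >= 22 | h_frac < 6
    a <- (h_frac[night] - 22) %% 24
    a2 <- (a + profile$bedtime_shift_hours) %% 8
    h2 <- (22 + a2) %% 24
    day_bump <- integer(sum(night))
    day_bump[h_frac[night] >= 22 & h2 < 22] <- 1L  # crossed midnight forward
    day_bump[h_frac[night] < 6 & h2 >= 22] <- -1L  # wrapped back to evening
    start_sec[night] <- h2 * 3600
    dates[night] <- dates[night] + day_bump
  }
  midnights <- as.POSIXct(paste(dates, "00:00:00"), tz = tz)

  session_id <- rep(seq_len(k), sizes)
  gaps <- 10^rnorm(sum(sizes) - k, profile$in_session_log10gap_mean,
                   profile$in_session_log10gap_sd)
  offsets <- numeric(sum(sizes))
  pos <- cumsum(sizes)
  first_of_session <- c(1L, head(pos, -1) + 1L)
  gap_full <- numeric(sum(sizes))
  gap_full[-first_of_session] <- gaps
  offsets <- stats::ave(gap_full, session_id, FUN = cumsum)

  ts <- midnights[session_id] + start_sec[session_id] + offsets
  keep <- ts < window_bounds(windows, which)[2] & ts >= window_bounds(windows, which)[1]

  platform <- ifelse(runif(k) < profile$platform_mix, "youtube", "google_search")[session_id]
  action <- character(length(ts))
  is_yt <- platform == "youtube"
  action[is_yt] <- sample(c("video_watch", "youtube_search"), sum(is_yt),
                          replace = TRUE, prob = c(0.9, 0.1))
  action[!is_yt] <- sample(c("search_query", "url_visit"), sum(!is_yt),
                           replace = TRUE, prob = c(0.85, 0.15))
  txt <- draw_texts(length(ts), cat_w)
  tibble(
    timestamp = ts, platform = platform, action = action,
    text = txt$text, url = draw_url(txt$category, action)
  )[keep, ]
}

#' Simulate one participant's activity log
#'
#' Generates a timestamped event stream over the before, excluded and after
#' windows from a [behavior_profile()]. The total event count in each window
#' is Poisson with mean `daily_rate * days`; events arrive in sessions
#' (geometric lengths, lognormal within-session gaps) whose starts follow the
#' circadian hour weights, rotated by `bedtime_shift_hours` at night in the
#' after window. Alongside the events, a ground-truth ledger row records the
#' injected shift parameters before any sampling noise.
#'
#' @param profile A [behavior_profile()].
#' @param windows An [analysis_windows()] object.
#' @param seed Integer seed; generation is fully reproducible and leaves the
#'   global RNG state untouched.
#' @param participant_id Identifier stamped on the events.
#' @return A list with `events` (tibble) and `ledger` (one-row tibble).
#' @export
generate_participant <- function(profile, windows, seed, participant_id = "p01") {
  stopifnot(inherits(profile, "behavior_profile"), inherits(windows, "analysis_windows"))
  events <- withr::with_seed(seed, {
    parts <- lapply(c("before", "excluded", "after"), function(w) {
      simulate_window(profile, windows, w, windows$tz)
    })
    bind_rows(parts)
  })
  events <- events |>
    mutate(participant_id = participant_id, .before = 1) |>
    arrange(.data$timestamp)
  w_after <- rotate_night_mass(profile$circadian_weights, profile$bedtime_shift_hours)
  ratio_after <- (w_after * profile$daily_rate_after) /
    pmax(profile$circadian_weights * profile$daily_rate, 1e-12)
  ledger <- tibble(
    participant_id = participant_id,
    bedtime_shift_hours = profile$bedtime_shift_hours,
    rate_ratio_after = profile$daily_rate_after / profile$daily_rate,
    session_p_before = profile$session_length_p,
    session_p_after = profile$session_length_p_after,
    true_tau_log10_google_search = true_gap_boundary_log10(profile),
    true_tau_log10_youtube = true_gap_boundary_log10(profile),
    hour_rate_ratio = list(ratio_after),
    category_weight_ratio = list(
      profile$category_weights_after /
        pmax(profile$category_weights[names(profile$category_weights_after)], 1e-12)
    )
  )
  list(events = validate_events(events), ledger = ledger)
}

#' Link survey score changes to behavioral shift features
#'
#' Builds two-wave PHQ-9/GAD-7 panels whose score deltas are a linear
#' combination of the standardized shift features plus Gaussian noise, with
#' loadings equal to the target correlations and the noise scaled
#' analytically to `sqrt(1 - sum(rho^2))`, so that the population
#' correlation between each feature and the delta equals its target `rho`
#' when the features are uncorrelated (for correlated features the induced
#' correlations are `R rho`, slightly above the targets). The request is
#' rejected as infeasible when the sum of squared `rho` exceeds 1. With a
#' single feature at `rho = 1` and no extra noise the continuous latent
#' delta is an exact linear function of the feature.
#'
#' @param features Wide tibble: `participant_id` plus numeric feature columns.
#' @param effects_phq9,effects_gad7 Named numeric vectors of target
#'   correlations (names must be feature columns), `|rho| <= 1`.
#' @param noise_sd Extra measurement noise (score points) added on top of the
#'   analytic noise channel; nonzero values attenuate the targets.
#' @param seed Integer seed.
#' @param delta_mean,delta_sd Location/scale (score points) of the latent
#'   deltas, recycled for the two instruments.
#' @param round_scores Produce integer, range-clipped scores (the survey
#'   instruments' scales)? Set `FALSE` to keep the exact continuous link, for
#'   calibration studies.
#' @return A survey tibble (a valid [survey_panel()] when `round_scores` is
#'   `TRUE`) with demographics columns.
#' @export
link_scores <- function(features, effects_phq9, effects_gad7 = effects_phq9,
                        noise_sd = 0, seed = 1,
                        delta_mean = c(1.5, 1.5), delta_sd = c(4, 3.5),
                        round_scores = TRUE) {
  features <- as_tibble(features)
  n <- nrow(features)
  if (n < 3) abort("link_scores() needs at least 3 participants")
  delta_mean <- rep_len(delta_mean, 2)
  delta_sd <- rep_len(delta_sd, 2)

  latent <- function(effects, sub_seed) {
    if (any(abs(effects) > 1)) abort("target correlations must satisfy |rho| <= 1")
    miss <- setdiff(names(effects), names(features))
    if (length(miss)) abort(paste("effects name unknown features:", paste(miss, collapse = ", ")))
    Z <- scale(as.matrix(features[names(effects)]))
    if (any(!is.finite(Z))) abort("features must be non-constant and complete for the score link")
    b <- effects
    s2 <- sum(effects^2)
    if (s2 > 1 + 1e-8) {
      abort("infeasible target correlations: sum of squared rho exceeds 1")
    }
    withr::with_seed(sub_seed, {
      drop(Z %*% b) + rnorm(n, 0, sqrt(max(0, 1 - s2))) + rnorm(n, 0, noise_sd)
    })
  }

  y_phq <- latent(effects_phq9, child_seed(seed, 101))
  y_gad <- latent(effects_gad7, child_seed(seed, 202))

  finish <- function(y, mean_, sd_, base_mean, base_sd, lo, hi, sub_seed) {
    delta <- mean_ + sd_ * y
    withr::with_seed(sub_seed, {
      before <- rnorm(n, base_mean, base_sd)
    })
    if (round_scores) {
      before <- pmin(hi, pmax(lo, round(before)))
      after <- pmin(hi, pmax(lo, round(before + delta)))
    } else {
      after <- before + delta
    }
    list(before = before, after = after)
  }
  phq <- finish(y_phq, delta_mean[1], delta_sd[1], 8, 4, 0, 27, child_seed(seed, 303))
  gad <- finish(y_gad, delta_mean[2], delta_sd[2], 6, 3.5, 0, 21, child_seed(seed, 404))

  demo <- withr::with_seed(child_seed(seed, 505), tibble(
    gender = sample(c("female", "male", "nonbinary"), n, TRUE, prob = c(0.61, 0.35, 0.04)),
    year = sample(1:4, n, TRUE, prob = c(0.22, 0.41, 0.31, 0.06)),
    citizen = sample(c("yes", "no"), n, TRUE, prob = c(0.8, 0.2))
  ))
  out <- tibble(
    participant_id = features$participant_id,
    phq9_before = phq$before, phq9_after = phq$after,
    gad7_before = gad$before, gad7_after = gad$after
  ) |>
    bind_cols(demo)
  if (round_scores) {
    survey_panel(out)
  } else {
    out |>
      mutate(
        delta_phq9 = .data$phq9_after - .data$phq9_before,
        delta_gad7 = .data$gad7_after - .data$gad7_before,
        alarming_phq9 = .data$delta_phq9 >= 5,
        alarming_gad7 = .data$delta_gad7 >= 5
      )
  }
}

#' Cohort configuration for the synthetic generator
#'
#' Gathers everything [generate_cohort()] needs: cohort size, analysis
#' windows, the base behavior profile, the per-participant heterogeneity of
#' the injected shifts, and the target feature-score correlations for the
#' survey link. The defaults describe a 49-person cohort with a mean bedtime
#' delay of about 45 minutes, mildly increased post-boundary volume and
#' burstier video sessions, and temporal-feature-only score signal.
#'
#' @param n_participants Cohort size.
#' @param windows An [analysis_windows()] object.
#' @param seed Integer master seed; all generation randomness derives from it.
#' @param profile Base [behavior_profile()] shared by the cohort.
#' @param effects Named list with `phq9` and `gad7` target-correlation
#'   vectors, keyed by wide feature name (e.g. `hourly_change_3`).
#' @param noise_sd Extra score noise passed to [link_scores()].
#' @param heterogeneity List of spread parameters for the per-participant
#'   injected shifts: `bedtime_mean`, `bedtime_sd`, `bedtime_range`,
#'   `rate_meanlog`, `rate_sdlog`, `burst_meanlog`, `burst_sdlog`,
#'   `semantic_sdlog`, `semantic_categories`.
#' @param round_scores Passed to [link_scores()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 49,
                          windows = analysis_windows(),
                          seed = 42,
                          profile = behavior_profile(),
                          effects = list(
                            phq9 = c(hourly_change_3 = 0.55,
                                     last_seen_shift_5 = 0.40,
                                     sei_change_youtube = 0.30),
                            gad7 = c(hourly_change_3 = 0.50,
                                     last_seen_shift_4 = 0.35,
                                     sei_change_youtube = 0.30)
                          ),
                          noise_sd = 0,
                          heterogeneity = list(
                            bedtime_mean = 0.75, bedtime_sd = 0.6,
                            bedtime_range = c(-0.5, 2.25),
                            rate_meanlog = log(1.05), rate_sdlog = 0.15,
                            burst_meanlog = log(1.25), burst_sdlog = 0.3,
                            semantic_sdlog = 0.35,
                            semantic_categories = c("death", "anxiety", "sadness",
                                                    "adult", "news", "work", "money")
                          ),
                          round_scores = TRUE) {
  stopifnot(n_participants >= 1, inherits(windows, "analysis_windows"),
            inherits(profile, "behavior_profile"))
  for (eff in effects) {
    if (any(abs(eff) > 1)) abort("effect correlations must satisfy |rho| <= 1")
  }
  structure(list(
    n_participants = as.integer(n_participants), windows = windows, seed = as.integer(seed),
    profile = profile, effects = effects, noise_sd = noise_sd,
    heterogeneity = heterogeneity, round_scores = round_scores
  ), class = "cohort_config")
}

clamp <- function(x, range) pmin(range[2], pmax(range[1], x))

# draw per-participant injected-shift parameters
draw_participant_profiles <- function(config) {
  h <- config$heterogeneity
  n <- config$n_participants
  base <- config$profile
  withr::with_seed(child_seed(config$seed, 1), {
    bedtime <- clamp(rnorm(n, h$bedtime_mean, h$bedtime_sd), h$bedtime_range)
    rate_mult <- stats::rlnorm(n, h$rate_meanlog, h$rate_sdlog)
    burst <- stats::rlnorm(n, h$burst_meanlog, h$burst_sdlog)
    sem_mult <- matrix(
      stats::rlnorm(n * length(h$semantic_categories), 0, h$semantic_sdlog),
      nrow = n, dimnames = list(NULL, h$semantic_categories)
    )
    lapply(seq_len(n), function(i) {
      cw_after <- base$category_weights
      cw_after[h$semantic_categories] <- cw_after[h$semantic_categories] * sem_mult[i, ]
      behavior_profile(
        daily_rate = base$daily_rate,
        circadian_weights = base$circadian_weights,
        bedtime_shift_hours = bedtime[i],
        session_length_p = base$session_length_p,
        in_session_log10gap_mean = base$in_session_log10gap_mean,
        in_session_log10gap_sd = base$in_session_log10gap_sd,
        between_session_log10gap_mean = base$between_session_log10gap_mean,
        between_session_log10gap_sd = base$between_session_log10gap_sd,
        category_weights = base$category_weights,
        category_weights_after = cw_after / sum(cw_after),
        platform_mix = base$platform_mix,
        daily_rate_after = base$daily_rate * rate_mult[i],
        session_length_p_after = clamp(base$session_length_p / burst[i], c(0.02, 1))
      )
    })
  })
}

#' Generate a full synthetic cohort
#'
#' Simulates every participant's activity log, fits the pooled per-platform
#' session thresholds, extracts the full behavioral shift feature table with
#' the package's own pipeline, links two-wave survey scores to the features
#' at the configured target correlations, and records all injected
#' ground-truth parameters in a ledger. Identical configurations (including
#' the seed) produce identical cohorts.
#'
#' @param config A [cohort_config()].
#' @return An object of class `synthetic_cohort`: a list with `events`,
#'   `survey`, `features` (tidy), `taus` (named per-platform thresholds, in
#'   seconds), `ledger`, and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  profiles <- draw_participant_profiles(config)
  ids <- sprintf("p%02d", seq_len(config$n_participants))
  sims <- lapply(seq_along(profiles), function(i) {
    generate_participant(profiles[[i]], config$windows,
                         seed = child_seed(config$seed, 1000 + i),
                         participant_id = ids[i])
  })
  events <- bind_rows(lapply(sims, `[[`, "events"))
  ledger <- bind_rows(lapply(sims, `[[`, "ledger"))

  # pseudo zero policy keeps sparse night hours defined so the score link
  # always sees complete feature columns
  features <- extract_features(events, config$windows, zero_policy = "pseudo",
                               quiet = TRUE)
  taus <- attr(features, "taus")

  wide <- features_wide(features)
  needed <- unique(c(names(config$effects$phq9), names(config$effects$gad7)))
  miss <- setdiff(needed, names(wide))
  if (length(miss)) abort(paste("effect features not produced:", paste(miss, collapse = ", ")))
  survey <- link_scores(
    wide[c("participant_id", needed)],
    effects_phq9 = config$effects$phq9, effects_gad7 = config$effects$gad7,
    noise_sd = config$noise_sd, seed = child_seed(config$seed, 2),
    round_scores = config$round_scores
  )
  ledger$effects_phq9 <- list(config$effects$phq9)
  ledger$effects_gad7 <- list(config$effects$gad7)

  structure(
    list(events = events, survey = survey, features = features,
         taus = taus, ledger = ledger, config = config),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", x$config$n_participants, "participants,",
      nrow(x$events), "events\n")
  cat("  taus:", paste(sprintf("%s=%.1fs", names(x$taus), x$taus), collapse = ", "), "\n")
  cat("  seed:", x$config$seed, "\n")
  invisible(x)
}

#' Serialize and restore a cohort configuration
#'
#' Round-trips a [cohort_config()] through YAML so that a regenerated cohort
#' is identical to the original.
#'
#' @param config A `cohort_config`.
#' @param path YAML file path.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  p <- config$profile
  yaml::write_yaml(list(
    n_participants = config$n_participants,
    seed = config$seed,
    noise_sd = config$noise_sd,
    round_scores = config$round_scores,
    windows = list(
      before = as.character(config$windows$before),
      excluded = as.character(config$windows$excluded),
      after = as.character(config$windows$after),
      tz = config$windows$tz
    ),
    profile = list(
      daily_rate = p$daily_rate,
      circadian_weights = p$circadian_weights,
      bedtime_shift_hours = p$bedtime_shift_hours,
      session_length_p = p$session_length_p,
      in_session_log10gap_mean = p$in_session_log10gap_mean,
      in_session_log10gap_sd = p$in_session_log10gap_sd,
      between_session_log10gap_mean = p$between_session_log10gap_mean,
      between_session_log10gap_sd = p$between_session_log10gap_sd,
      category_weights = as.list(p$category_weights),
      category_weights_after = as.list(p$category_weights_after),
      platform_mix = p$platform_mix,
      daily_rate_after = p$daily_rate_after,
      session_length_p_after = p$session_length_p_after
    ),
    effects = lapply(config$effects, as.list),
    heterogeneity = config$heterogeneity
  ), path, precision = 17)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  pr <- y$profile
  cohort_config(
    n_participants = y$n_participants,
    windows = analysis_windows(
      before = unlist(y$windows$before), excluded = unlist(y$windows$excluded),
      after = unlist(y$windows$after), tz = y$windows$tz
    ),
    seed = y$seed,
    profile = behavior_profile(
      daily_rate = pr$daily_rate,
      circadian_weights = unlist(pr$circadian_weights),
      bedtime_shift_hours = pr$bedtime_shift_hours,
      session_length_p = pr$session_length_p,
      in_session_log10gap_mean = pr$in_session_log10gap_mean,
      in_session_log10gap_sd = pr$in_session_log10gap_sd,
      between_session_log10gap_mean = pr$between_session_log10gap_mean,
      between_session_log10gap_sd = pr$between_session_log10gap_sd,
      category_weights = unlist(pr$category_weights),
      category_weights_after = unlist(pr$category_weights_after),
      platform_mix = pr$platform_mix,
      daily_rate_after = pr$daily_rate_after,
      session_length_p_after = pr$session_length_p_after
    ),
    effects = lapply(y$effects, unlist),
    noise_sd = y$noise_sd,
    heterogeneity = utils::modifyList(
      cohort_config()$heterogeneity,
      lapply(y$heterogeneity, function(v) if (is.list(v)) unlist(v) else v)
    ),
    round_scores = y$round_scores
  )
}

#' Write the ground-truth ledger as JSON
#'
#' @param cohort A `synthetic_cohort` (or its `ledger` tibble).
#' @param path Output JSON path.
#' @export
write_ledger <- function(cohort, path) {
  ledger <- if (inherits(cohort, "synthetic_cohort")) cohort$ledger else cohort
  jsonlite::write_json(ledger, path, auto_unbox = FALSE, digits = NA, dataframe = "rows")
  invisible(path)
}
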