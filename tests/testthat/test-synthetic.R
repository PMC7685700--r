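test_that("event counts follow the configured volume (Poisson band)", {
  w <- analysis_windows()
  pr <- behavior_profile(daily_rate = 50)
  # before window: 60 days -> mean 3000; central 99% Poisson band
  band <- qpois(c(0.005, 0.995), lambda = 50 * 60)
  hits <- vapply(1:5, function(seed) {
    g <- generate_participant(pr, w, seed = seed)
    seg <- segment_events(g$events, w, quiet = TRUE)
    sum(seg$window == "before")
  }, numeric(1))
  expect_true(all(hits >= band[1] & hits <= band[2]))
})

test_that("generation is deterministic in the seed and varies across seeds", {
  w <- short_windows()
  pr <- behavior_profile(daily_rate = 20)
  a <- generate_participant(pr, w, seed = 5)
  b <- generate_participant(pr, w, seed = 5)
  expect_identical(a$events, b$events)
  expect_identical(a$ledger, b$ledger)
  c <- generate_participant(pr, w, seed = 6)
  expect_false(identical(a$events, c$events))
  # the generator must not disturb the global RNG stream
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(generate_participant(pr, w, seed = 9)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("events land in all three windows, time-ordered, schema-valid", {
  w <- analysis_windows()
  g <- generate_participant(behavior_profile(daily_rate = 10), w, seed = 2)
  expect_false(is.unsorted(g$events$timestamp))
  seg <- segment_events(g$events, w, quiet = TRUE)
  expect_true(all(c("before", "excluded", "after") %in% seg$window))
  expect_equal(sum(seg$window == "out_of_range"), 0)
  expect_silent(validate_events(g$events))
  expect_error(
    generate_participant(behavior_profile(daily_rate = 0), w, 1),
    "positive"
  )
})

test_that("without an injected shift, before and after circadian shapes agree", {
  w <- analysis_windows()
  g <- generate_participant(behavior_profile(daily_rate = 60), w, seed = 3)
  seg <- segment_events(g$events, w, quiet = TRUE)
  hb <- hourly_histogram(seg[seg$window == "before", ], 60)
  ha <- hourly_histogram(seg[seg$window == "after", ], 64)
  pb <- hb$value / sum(hb$value)
  pa <- ha$value / sum(ha$value)
  # session clustering makes the effective sample the ~1100 session starts
  # per window; per-bin proportions then differ by a few sd ~ 0.013 at most
  expect_lt(max(abs(pb - pa)), 0.05)
  expect_gt(cor(pb, pa), 0.9)
})

test_that("a bedtime shift moves night mass later without changing totals", {
  wts <- phenoshift:::default_circadian_weights()
  rot <- phenoshift:::rotate_night_mass(wts, 1.5)
  expect_equal(sum(rot), sum(wts), tolerance = 1e-12)
  expect_equal(rot[7:22], wts[7:22]) # daytime bins 6:00-21:00 untouched
  # mass at 23:00-01:00 grows, the 22:00 leading edge shrinks
  expect_lt(rot[23], wts[23])
  expect_gt(rot[1] + rot[2], wts[1] + wts[2])
})

test_that("the log-gap histogram is bimodal with a valley near the ledger boundary", {
  w <- analysis_windows()
  g <- generate_participant(behavior_profile(daily_rate = 85), w, seed = 13)
  seg <- segment_events(g$events, w, quiet = TRUE)
  gaps <- log10(c(
    phenoshift:::platform_gaps(seg[seg$window == "before", ], "youtube"),
    phenoshift:::platform_gaps(seg[seg$window == "after", ], "youtube")
  ))
  dens <- density(gaps, n = 512)
  truth <- g$ledger$true_tau_log10_youtube
  near <- dens$y[abs(dens$x - truth) < 0.3]
  in_peak <- max(dens$y[dens$x < truth - 0.5])
  out_peak <- max(dens$y[dens$x > truth + 0.5])
  expect_lt(min(near), 0.5 * in_peak)
  expect_lt(min(near), 0.5 * out_peak)
})

test_that("score link achieves exact correlation in the noiseless linear case", {
  withr::with_seed(1, feats <- tibble::tibble(
    participant_id = sprintf("p%02d", 1:30), f1 = rnorm(30)
  ))
  sv <- link_scores(feats, effects_phq9 = c(f1 = 1), noise_sd = 0, seed = 2,
                    round_scores = FALSE)
  expect_equal(cor(sv$delta_phq9, feats$f1), 1, tolerance = 1e-9)
  svneg <- link_scores(feats, effects_phq9 = c(f1 = -1), noise_sd = 0, seed = 2,
                       round_scores = FALSE)
  expect_equal(cor(svneg$delta_phq9, feats$f1), -1, tolerance = 1e-9)
})

test_that("null effects stay inside the Fisher-z 99% bound", {
  n <- 120
  bound <- tanh(qnorm(0.995) / sqrt(n - 3))
  withr::with_seed(5, feats <- tibble::tibble(
    participant_id = sprintf("p%03d", 1:n), f1 = rnorm(n), f2 = rnorm(n)
  ))
  fails <- 0
  for (seed in 1:20) {
    sv <- link_scores(feats, effects_phq9 = c(f1 = 0, f2 = 0), seed = seed,
                      round_scores = FALSE)
    r <- abs(cor(sv$delta_phq9, feats$f1))
    if (r > bound) fails <- fails + 1
  }
  expect_lte(fails, 2) # ~1% expected exceedance per draw
})

test_that("infeasible correlation targets and range violations are rejected", {
  feats <- tibble::tibble(participant_id = c("a", "b", "c", "d"),
                          f1 = c(1, 2, 3, 4), f2 = c(2, 1, 4, 3))
  expect_error(
    link_scores(feats, effects_phq9 = c(f1 = 0.9, f2 = 0.9), seed = 1),
    "infeasible"
  )
  expect_error(link_scores(feats, effects_phq9 = c(f1 = 1.2), seed = 1), "rho")
  expect_error(link_scores(feats[1:2, ], effects_phq9 = c(f1 = 0.5), seed = 1),
               "at least 3")
  # integer mode produces a valid survey panel within instrument ranges
  sv <- link_scores(feats, effects_phq9 = c(f1 = 0.5), seed = 3)
  expect_true(all(sv$phq9_before >= 0 & sv$phq9_before <= 27))
  expect_true(all(sv$gad7_after >= 0 & sv$gad7_after <= 21))
  expect_equal(sv$delta_phq9, sv$phq9_after - sv$phq9_before)
})

test_that("cohorts are reproducible, seed-sensitive, and config round-trips", {
  cfg <- tiny_cohort_config(n = 10, seed = 7, daily_rate = 15)
  c1 <- generate_cohort(cfg)
  expect_equal(nrow(c1$ledger), 10)
  expect_equal(sort(unique(c1$events$participant_id)), sprintf("p%02d", 1:10))
  c2 <- generate_cohort(cfg)
  expect_identical(c1$events, c2$events)
  expect_identical(c1$survey, c2$survey)
  c3 <- generate_cohort(tiny_cohort_config(n = 10, seed = 8, daily_rate = 15))
  expect_false(identical(c1$events, c3$events))

  path <- withr::local_tempfile(fileext = ".yml")
  write_cohort_config(cfg, path)
  c4 <- generate_cohort(read_cohort_config(path))
  expect_identical(c1$events, c4$events)
  expect_identical(c1$survey, c4$survey)
})
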