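#' Cohort deterioration summary
#'
#' Descriptive counts and integer-rounded percentages: how many participants
#' reported any increase, and a clinically alarming increase (>= 5 points),
#' in each score; plus demographic breakdowns (gender, citizenship, school
#' year) within each any-increase group, each as a percentage of that group.
#'
#' @param survey A [survey_panel()] tibble, optionally with `gender`,
#'   `citizen`, `year` columns.
#' @return A tibble of class `cohort_summary` with columns `group`,
#'   `measure`, `count`, `denominator`, `percent` (`round()` to the nearest
#'   integer).
#' @examples
#' sv <- tibble::tibble(
#'   participant_id = paste0("p", 1:4),
#'   phq9_before = c(5, 5, 5, 5), phq9_after = c(11, 7, 5, 4),
#'   gad7_before = c(4, 4, 4, 4), gad7_after = c(10, 9, 4, 3)
#' )
#' summarize_cohort(survey_panel(sv))
#' @export
summarize_cohort <- function(survey) {
  survey <- survey_panel(survey)
  n <- nrow(survey)
  pct <- function(count, denom) ifelse(denom > 0, round(count / denom * 100), NA_real_)
  row <- function(group, measure, count, denom) {
    tibble(group = group, measure = measure, count = as.integer(count),
           denominator = as.integer(denom), percent = pct(count, denom))
  }
  out <- list(
    row("cohort", "n", n, n),
    row("cohort", "phq9_increase", sum(survey$delta_phq9 > 0), n),
    row("cohort", "gad7_increase", sum(survey$delta_gad7 > 0), n),
    row("cohort", "phq9_alarming", sum(survey$alarming_phq9), n),
    row("cohort", "gad7_alarming", sum(survey$alarming_gad7), n)
  )
  demo_rows <- function(sub, group) {
    m <- nrow(sub)
    rows <- list(row(group, "n", m, n))
    if ("gender" %in% names(sub)) {
      rows <- c(rows, list(row(group, "female", sum(sub$gender == "female"), m)))
    }
    if ("citizen" %in% names(sub)) {
      rows <- c(rows, list(row(group, "us_citizen", sum(sub$citizen == "yes"), m)))
    }
    if ("year" %in% names(sub)) {
      rows <- c(rows, lapply(1:4, function(yy) {
        row(group, paste0("year_", yy), sum(sub$year == yy), m)
      }))
    }
    rows
  }
  if (any(c("gender", "citizen", "year") %in% names(survey))) {
    out <- c(out,
      demo_rows(survey[survey$delta_phq9 > 0, ], "phq9_increased"),
      demo_rows(survey[survey$delta_gad7 > 0, ], "gad7_increased")
    )
    if ("citizen" %in% names(survey)) {
      out <- c(out, list(row("cohort", "us_citizen", sum(survey$citizen == "yes"), n)))
    }
    if ("gender" %in% names(survey)) {
      out <- c(out, list(row("cohort", "female", sum(survey$gender == "female"), n)))
    }
  }
  res <- bind_rows(out)
  structure(res, class = c("cohort_summary", class(res)))
}

#' Group time series of daily short-interval totals
#'
#' Splits the cohort by clinically alarming deterioration (score increase
#' >= 5 vs < 5), totals the short event intervals on one platform per day
#' and group across the whole observation span, and smooths each series with
#' a trailing 7-day moving average (shorter head windows average over the
#' days available). Each short interval is dated by its second event, on the
#' local clock.
#'
#' @param events Cohort event tibble.
#' @param survey A [survey_panel()] tibble.
#' @param windows [analysis_windows()] (sets the observation span and
#'   timezone; the excluded buffer is displayed, not dropped, in this
#'   descriptive view).
#' @param score `"phq9"` or `"gad7"` (selects the alarming flag).
#' @param tau Session threshold in seconds.
#' @param platform Platform whose short intervals are counted.
#' @param window Moving-average length in days.
#' @return A tibble of class `group_series` with `date`, `group`
#'   (`"alarming"` / `"not_alarming"`), `total`, `moving_avg`; group sizes
#'   attached as attribute `group_sizes`.
#' @export
group_moving_average <- function(events, survey, windows, score = c("phq9", "gad7"),
                                 tau, platform = "youtube", window = 7) {
  score <- match.arg(score)
  survey <- survey_panel(survey)
  flag_col <- paste0("alarming_", score)
  groups <- survey |>
    transmute(.data$participant_id,
              group = ifelse(.data[[flag_col]], "alarming", "not_alarming"))
  for (g in c("alarming", "not_alarming")) {
    if (!any(groups$group == g)) warn(paste("empty group:", g, "- series will be all zero"))
  }

  span <- seq(windows$before[1], windows$after[2] - 1, by = "day")
  ev <- events[events$platform == platform, ]
  ev <- ev[order(ev$participant_id, ev$timestamp), ]
  gaps_ok <- ev$participant_id[-1] == ev$participant_id[-nrow(ev)] &
    as.numeric(diff(ev$timestamp), units = "secs") < tau
  sei <- tibble(
    participant_id = ev$participant_id[-1][gaps_ok],
    date = as_date(with_tz(ev$timestamp[-1][gaps_ok], windows$tz))
  ) |>
    inner_join(groups, by = "participant_id") |>
    count(.data$date, .data$group, name = "total")

  full <- tidyr::expand_grid(date = span, group = c("alarming", "not_alarming")) |>
    left_join(sei, by = c("date", "group")) |>
    mutate(total = tidyr::replace_na(.data$total, 0L)) |>
    group_by(.data$group) |>
    arrange(.data$date, .by_group = TRUE) |>
    mutate(moving_avg = zoo::rollapplyr(.data$total, window, mean, partial = TRUE)) |>
    ungroup()
  structure(full,
    class = c("group_series", class(full)),
    group_sizes = table(groups$group), score = score
  )
}

#' Run the full analysis pipeline from a config file
#'
#' Orchestrates simulate (optional) -> read -> segment -> feature extraction
#' -> correlation battery -> regression models -> descriptive reports, and
#' writes all artifacts into one output directory: `events.jsonl`,
#' `survey.csv`, `features.csv`, `correlations.csv`, `regression.json`,
#' `summary.json`, `series.csv`, `ledger.json` (when simulating) and
#' `run_log.txt`. Outputs are stamped with the seed and a checksum of the
#' resolved configuration; a rerun of the same config reproduces them
#' byte-identically. Any stage failure aborts with the stage name.
#'
#' The YAML config supports: `seed`, `out_dir`, `simulate` (logical),
#' `n_participants`, `windows` (start/end dates and `tz`), `events_file` /
#' `survey_file` (when not simulating), `zero_policy`, `alpha`, and `noise_sd`.
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#' @param out_dir Output directory (overrides the config's `out_dir`).
#' @return The output directory path, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  out_dir <- out_dir %||% cfg$out_dir %||% abort("no output directory configured")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed %||% 1)
  cfg_hash <- config_checksum(cfg)
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", file = log_path, append = TRUE, sep = "")
  cat(sprintf("pipeline run: seed=%d config_checksum=%s\n", seed, cfg_hash),
      file = log_path)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  windows <- stage("windows", {
    if (is.null(cfg$windows)) analysis_windows() else analysis_windows(
      before = unlist(cfg$windows$before), excluded = unlist(cfg$windows$excluded),
      after = unlist(cfg$windows$after), tz = cfg$windows$tz %||% "America/New_York"
    )
  })

  if (isTRUE(cfg$simulate)) {
    cohort <- stage("simulate", {
      cc <- cohort_config(
        n_participants = cfg$n_participants %||% 49,
        windows = windows, seed = seed,
        profile = behavior_profile(daily_rate = cfg$daily_rate %||% 85),
        noise_sd = cfg$noise_sd %||% 0
      )
      generate_cohort(cc)
    })
    events <- cohort$events
    survey <- cohort$survey
    stage("write_inputs", {
      write_events(events, file.path(out_dir, "events.jsonl"), tz = windows$tz)
      write_survey(survey, file.path(out_dir, "survey.csv"))
      write_ledger(cohort, file.path(out_dir, "ledger.json"))
    })
    features <- cohort$features
    taus <- cohort$taus
  } else {
    events <- stage("read_events", {
      if (is.null(cfg$events_file) || !file.exists(cfg$events_file)) {
        abort(paste("events file not found:", cfg$events_file %||% "<unset>"))
      }
      read_events(cfg$events_file)
    })
    survey <- stage("read_survey", {
      if (is.null(cfg$survey_file) || !file.exists(cfg$survey_file)) {
        abort(paste("survey file not found:", cfg$survey_file %||% "<unset>"))
      }
      read_survey(cfg$survey_file)
    })
    features <- stage("features", {
      extract_features(events, windows,
                       zero_policy = cfg$zero_policy %||% "strict", quiet = TRUE)
    })
    taus <- attr(features, "taus")
  }
  logf("events: %d rows; survey: %d participants", nrow(events), nrow(survey))
  logf("taus: %s", paste(sprintf("%s=%.2f", names(taus), taus), collapse = ", "))
  logf("features: %d rows (%d participants)", nrow(features),
       length(unique(features$participant_id)))

  stage("features_out", write_features(features, file.path(out_dir, "features.csv")))

  battery <- stage("correlations", correlation_battery(features, survey))
  stage("correlations_out", write_correlations(battery, file.path(out_dir, "correlations.csv")))
  logf("correlations: %d cells, %d significant", nrow(battery), sum(battery$significant))

  regression <- stage("models", {
    alpha <- cfg$alpha %||% 1e-4
    specs <- list(temporal = feature_vector_spec("temporal"),
                  semantic = feature_vector_spec("semantic"))
    reports <- list()
    for (sp in names(specs)) {
      Xm <- build_feature_matrix(features, specs[[sp]], quiet = TRUE)
      sv <- survey[match(rownames(Xm), survey$participant_id), ]
      for (sc in c("delta_phq9", "delta_gad7")) {
        for (md in c("ols", "lasso")) {
          rep_ <- loo_evaluate(Xm, sv[[sc]], model_config(md, alpha = alpha),
                               target = sc)
          reports[[paste(sp, sc, md, sep = ".")]] <- list(
            spec = sp, target = sc, model = md, alpha = alpha,
            mse = rep_$mse, r2 = rep_$r2,
            per_split_errors = rep_$per_split_errors,
            coefficients = as.list(rep_$coefficients),
            intercept = rep_$intercept
          )
        }
      }
    }
    reports
  })
  stage("models_out", jsonlite::write_json(
    list(seed = seed, config_checksum = cfg_hash, models = regression),
    file.path(out_dir, "regression.json"), auto_unbox = TRUE, digits = NA
  ))

  summary_tbl <- stage("summary", summarize_cohort(survey))
  stage("summary_out", jsonlite::write_json(
    list(seed = seed, config_checksum = cfg_hash, summary = summary_tbl),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows"
  ))

  series <- stage("series", {
    group_moving_average(events, survey, windows, score = "phq9",
                         tau = taus[["youtube"]])
  })
  stage("series_out", utils::write.csv(
    as.data.frame(series), file.path(out_dir, "series.csv"), row.names = FALSE
  ))
  logf("done: artifacts in %s", out_dir)
  invisible(out_dir)
}

# order-stable checksum of the resolved config (position-weighted sum over
# its YAML dump; cheap but sensitive to any byte change)
config_checksum <- function(cfg) {
  s <- utf8ToInt(yaml::as.yaml(cfg[order(names(cfg))]))
  h <- sum(s * ((seq_along(s) - 1) %% 97 + 1)) %% 2147483647
  sprintf("%08x", as.integer(h))
}
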