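#' Seasonal slopes for a feature
#'
#' For each participant and calendar year, the slope of the line connecting
#' the before-window feature value to the after-window value, in feature
#' units per day. The window midpoints are used as the x-coordinates so the
#' 2019 and 2020 constructions are directly comparable.
#'
#' @param before_value,after_value Numeric per-participant feature values in
#'   the two windows.
#' @param windows The year's [analysis_windows()].
#' @return Numeric slopes (units/day).
#' @export
window_slope <- function(before_value, after_value, windows) {
  dt <- as.numeric(difftime(window_midpoint(windows, "after"),
                            window_midpoint(windows, "before"), units = "days"))
  (after_value - before_value) / dt
}

#' Paired test of year-over-year slope change
#'
#' Tests whether the within-year slope of a behavioral feature differs
#' between two years (for example 2020 vs the seasonal-control 2019), with a
#' two-tailed paired t-test across participants. A significant result means
#' the year's behavior change is not explained by seasonal recurrence.
#'
#' @param s_prev,s_curr Numeric slope vectors (same participants, paired),
#'   or a data frame with columns `s_2019`/`s_2020` passed as `s_prev`.
#' @return A one-row tibble with `t`, `df`, `p_value`, `n`, `mean_diff`, and
#'   a `degenerate` flag. When all differences are zero the test is reported
#'   as `t = 0, p = 1`; a nonzero constant difference reports signed-infinite
#'   `t` with `p = 0`, both flagged degenerate.
#' @examples
#' paired_slope_test(c(1, 2, 3), c(2, 4, 6))
#' @export
paired_slope_test <- function(s_prev, s_curr = NULL) {
  if (is.data.frame(s_prev)) {
    s_curr <- s_prev$s_2020
    s_prev <- s_prev$s_2019
  }
  if (length(s_prev) != length(s_curr)) abort("slope vectors must be paired")
  ok <- is.finite(s_prev) & is.finite(s_curr)
  s_prev <- s_prev[ok]; s_curr <- s_curr[ok]
  n <- length(s_prev)
  if (n < 3) abort("paired_slope_test() needs at least 3 finite pairs")
  d <- s_curr - s_prev
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(tibble(t = 0, df = n - 1, p_value = 1, n = n, mean_diff = 0,
                    degenerate = TRUE))
    }
    return(tibble(t = sign(mean(d)) * Inf, df = n - 1, p_value = 0, n = n,
                  mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- t.test(s_curr, s_prev, paired = TRUE)
  tibble(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, n = n, mean_diff = mean(d), degenerate = FALSE
  )
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Product-moment correlation with a two-tailed p-value from the t transform
#' on `n - 2` degrees of freedom and a confidence interval from the Fisher z
#' transform.
#'
#' @param x,y Equal-length numeric vectors (`n >= 4`, both non-constant);
#'   incomplete pairs are dropped.
#' @param confidence Confidence level for the Fisher-z interval.
#' @return A one-row tibble `(r, ci_low, ci_high, p_value, n)`.
#' @examples
#' pearson_with_ci(1:10, (1:10) * 2 + 1)
#' @export
pearson_with_ci <- function(x, y, confidence = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) abort("pearson_with_ci() needs at least 4 complete pairs")
  if (sd(x) == 0) abort("`x` is constant; correlation undefined")
  if (sd(y) == 0) abort("`y` is constant; correlation undefined")
  ct <- cor.test(x, y, conf.level = confidence)
  tibble(
    r = unname(ct$estimate), ci_low = ct$conf.int[1], ci_high = ct$conf.int[2],
    p_value = ct$p.value, n = n
  )
}

#' Correlation battery over features, parameters and score deltas
#'
#' Computes one Pearson correlation (with Fisher-z CI) per combination of
#' feature/parameter cell and score delta, mirroring the layout of per-hour,
#' per-cutoff and per-platform correlation tables. Participants missing a
#' cell's feature value are dropped pairwise; cells with fewer than 4
#' complete pairs are reported as missing rows rather than errors.
#'
#' @param features Tidy feature table from [extract_features()] (or any
#'   tibble with `participant_id`, `feature_name`, `parameter`, `value`).
#' @param survey A [survey_panel()] tibble.
#' @param scores Score-delta columns to correlate against.
#' @param confidence Confidence level.
#' @param adjust Apply Benjamini-Hochberg adjustment across the battery and
#'   add a `p_adjusted` column? Off by default (raw p-values are reported).
#' @return A tibble of class `correlation_battery`: one row per
#'   (feature_name, parameter, score) with `r`, `ci_low`, `ci_high`,
#'   `p_value`, `n`, `significant` (raw p < 0.05).
#' @export
correlation_battery <- function(features, survey,
                                scores = c("delta_phq9", "delta_gad7"),
                                confidence = 0.95, adjust = FALSE) {
  miss <- setdiff(scores, names(survey))
  if (length(miss)) abort(paste("survey missing score columns:", paste(miss, collapse = ", ")))
  joined <- features |>
    inner_join(survey[c("participant_id", scores)], by = "participant_id")
  cells <- joined |>
    tidyr::pivot_longer(all_of(scores), names_to = "score", values_to = "delta") |>
    group_by(.data$feature_name, .data$parameter, .data$score)
  out <- cells |>
    summarise(
      res = list({
        ok <- is.finite(.data$value) & is.finite(.data$delta)
        v <- .data$value[ok]; d <- .data$delta[ok]
        if (length(v) < 4 || sd(v) == 0 || sd(d) == 0) {
          tibble(r = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 p_value = NA_real_, n = length(v))
        } else {
          pearson_with_ci(v, d, confidence)
        }
      }),
      .groups = "drop"
    ) |>
    tidyr::unnest("res") |>
    mutate(significant = !is.na(.data$p_value) & .data$p_value < 0.05)
  if (adjust) {
    out <- out |> mutate(p_adjusted = p.adjust(.data$p_value, method = "BH"))
  }
  structure(out, class = c("correlation_battery", class(out)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; provided for optional reporting
#' alongside the raw p-values that the battery reports by default.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values (monotone, bounded by 1).
#' @export
bh_adjust <- function(p) {
  p.adjust(p, method = "BH")
}

#' Write the correlation table CSV
#'
#' Layout mirrors the study's correlation tables:
#' `feature, parameter, score, r, ci_low, ci_high, p, n, significant_at_.05`.
#'
#' @param battery A [correlation_battery()] result.
#' @param path Output path.
#' @export
write_correlations <- function(battery, path) {
  out <- battery |>
    select(feature = "feature_name", "parameter", "score", "r",
           "ci_low", "ci_high", p = "p_value", "n",
           significant_at_.05 = "significant")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
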