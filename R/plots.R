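#' Plot an hourly activity profile
#'
#' @param object An `hourly_profile` from [hourly_histogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.hourly_profile <- function(object, ...) {
  ylab <- if (attr(object, "normalized")) "events per day" else "events"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$hour, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::scale_x_continuous(breaks = seq(0, 23, 3)) +
    ggplot2::labs(x = "local hour", y = ylab)
}

#' Plot per-hour relative activity change
#'
#' @param object An `hourly_change` from [hourly_relative_change()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.hourly_change <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$hour, y = .data$change_percent)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_x_continuous(breaks = seq(0, 23, 3)) +
    ggplot2::labs(x = "local hour", y = "relative change (%)")
}

#' Plot a correlation battery
#'
#' Correlation coefficients with their Fisher-z confidence intervals per
#' parameter, faceted by feature and score delta.
#'
#' @param object A [correlation_battery()] result.
#' @param features Optional subset of `feature_name`s to display.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.correlation_battery <- function(object, features = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(features)) df <- df[df$feature_name %in% features, ]
  df <- df[!is.na(df$r), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parameter, y = .data$r,
                                   color = .data$significant)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$score),
                        cols = ggplot2::vars(.data$feature_name),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "Pearson r (95% CI)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a deterioration-group time series
#'
#' The 7-day moving average of daily short-interval totals for the alarming
#' and non-alarming groups.
#'
#' @param object A [group_moving_average()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.group_series <- function(object, ...) {
  sizes <- attr(object, "group_sizes")
  lab <- sprintf("%s (n=%d)", names(sizes), as.integer(sizes))
  df <- as_tibble(object) |>
    mutate(group = factor(.data$group, levels = names(sizes), labels = lab))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$date, y = .data$moving_avg,
                                   color = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = "short intervals / day (7-day trailing mean)",
                  color = NULL,
                  title = paste("Deterioration groups by", attr(object, "score")))
}
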