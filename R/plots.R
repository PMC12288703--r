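#' Plot a randomization null distribution
#'
#' Histogram of the (exhaustive or Monte Carlo) randomization distribution of
#' the phase mean difference with the observed statistic marked.
#'
#' @param object A `rand_test` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rand_test
#' @export
autoplot.rand_test <- function(object, ...) {
  df <- tibble(statistic = object$distribution)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$statistic)) +
    ggplot2::geom_histogram(bins = min(30, max(5, object$n_permutations)),
                            fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed_stat,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(
      x = "phase mean difference (intervention - baseline)",
      y = "count",
      title = sprintf("%s randomization test (%s), p = %.3g",
                      if (object$scope == "combined") "Combined" else
                        "Individual",
                      object$method, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Plot day-level stress series by participant
#'
#' One panel per participant showing daily mean stress with the baseline
#' phase shaded and the intervention start marked.
#'
#' @param day_series Day-level tibble from [aggregate_daily()].
#' @return A ggplot object.
#' @export
plot_stress_series <- function(day_series) {
  stopifnot(all(c("participant_id", "day", "value", "start_day") %in%
                  names(day_series)))
  starts <- day_series %>% distinct(.data$participant_id, .data$start_day)
  ggplot2::ggplot(day_series, ggplot2::aes(x = .data$day, y = .data$value)) +
    ggplot2::geom_rect(
      data = starts,
      ggplot2::aes(xmin = -Inf, xmax = .data$start_day - 0.5,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "grey85", alpha = 0.6
    ) +
    ggplot2::geom_vline(data = starts,
                        ggplot2::aes(xintercept = .data$start_day - 0.5),
                        linetype = "dashed") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(size = 0.8, na.rm = TRUE) +
    ggplot2::facet_wrap(~participant_id) +
    ggplot2::labs(x = "study day", y = "mean daily stress (0-100)") +
    ggplot2::theme_minimal()
}

#' Plot a power curve
#'
#' Rejection rate against standardized effect size, one line per cohort
#' size, with the nominal level and the conventional 0.80 power target as
#' reference lines.
#'
#' @param object A `power_curve` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot power_curve
#' @export
autoplot.power_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$d, y = .data$rate,
                               colour = factor(.data$n_participants))) +
    ggplot2::geom_hline(yintercept = unique(object$alpha),
                        linetype = "dotted") +
    ggplot2::geom_hline(yintercept = 0.8, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lower,
                                      ymax = .data$ci_upper,
                                      fill = factor(.data$n_participants)),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "standardized effect size d", y = "rejection rate",
                  colour = "participants", fill = "participants") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
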