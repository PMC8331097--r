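#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_errorbar
#'   geom_path facet_wrap labs theme_minimal vars
#' @export
ggplot2::autoplot

#' Plot a circuit trajectory
#'
#' One panel per circuit variable (free y scales): firing rates in Hz,
#' concentrations in nM.
#'
#' @param object A `"circuit_trajectory"`.
#' @param vars_keep Variables to show (default: all eight).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot circuit_trajectory
#' @export
autoplot.circuit_trajectory <- function(object, vars_keep = .state_names, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), cols = -"time",
                              names_to = "variable", values_to = "value")
  long <- dplyr::filter(long, .data$variable %in% vars_keep)
  long$variable <- factor(long$variable, levels = .state_names)
  ggplot(long, aes(x = .data$time, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(vars(.data$variable), scales = "free_y") +
    labs(x = "time (s)", y = "firing rate (Hz) / concentration (nM)") +
    theme_minimal()
}

#' Plot an arm trace
#'
#' Endpoint trajectory in the horizontal workspace.
#'
#' @param object An `"arm_trace"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot arm_trace
#' @export
autoplot.arm_trace <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$x, y = .data$y)) +
    geom_path(linewidth = 0.2, alpha = 0.7) +
    labs(x = "x (m)", y = "y (m)") +
    theme_minimal()
}

#' Plot per-condition cohort summaries of a scenario
#'
#' Dopamine level and tremor amplitude (cohort mean, +/- 1 SD) by condition.
#'
#' @param object A `"scenario_result"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scenario_result
#' @export
autoplot.scenario_result <- function(object, ...) {
  s <- condition_summary(object)
  s$condition <- factor(s$condition, levels = s$condition)
  long <- dplyr::bind_rows(
    tibble(condition = s$condition, what = "dopamine (nM)",
           mean = s$da_mean, sd = s$da_sd),
    tibble(condition = s$condition, what = "tremor amplitude (m)",
           mean = s$tremor_mean, sd = s$tremor_sd)
  )
  long <- dplyr::filter(long, !is.na(.data$mean))
  ggplot(long, aes(x = .data$condition, y = .data$mean)) +
    geom_col(fill = "grey70") +
    geom_errorbar(aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
                  width = 0.2) +
    facet_wrap(vars(.data$what), scales = "free_y") +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' Plot the calibration fitness trace
#'
#' @param object A `"circuit_calibration"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot circuit_calibration
#' @export
autoplot.circuit_calibration <- function(object, ...) {
  ggplot(object$trace, aes(x = .data$generation, y = .data$best_score)) +
    geom_line() +
    labs(x = "generation", y = "best score") +
    theme_minimal()
}
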