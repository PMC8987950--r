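# ggplot2 visualisations.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a target set
#'
#' Targets in the midsagittal plane with the hip pivot and the reference
#' hand position for context.
#'
#' @param object A `reachvr_target_set` from [compute_target_set()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.reachvr_target_set <- function(object, ...) {
  a <- attr(object, "anthro")
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$anterior_m, y = .data$vertical_m)) +
    ggplot2::geom_point(size = 3, colour = "forestgreen") +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$theta_deg, "°")),
                       nudge_x = 0.05, size = 3) +
    ggplot2::annotate("point", x = 0, y = a$hip_height, shape = 4, size = 3) +
    ggplot2::annotate("text", x = 0.02, y = a$hip_height, label = "hip pivot",
                      hjust = 0, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "anterior (m)", y = "vertical (m)",
                  title = "Anthropometry-scaled target locations") +
    ggplot2::theme_minimal()
}

#' Plot a sampled ballistic trajectory
#'
#' @param object A `reachvr_trajectory` from [simulate_flight()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.reachvr_trajectory <- function(object, ...) {
  sol <- attr(object, "solution")
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$x_m, y = .data$z_m)) +
    ggplot2::geom_path(colour = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "anterior (m)", y = "vertical (m)",
                  title = sprintf("%s flight (v0 = %.2f m/s, alpha = %.1f°)",
                                  sol$mode, sol$v0, sol$alpha_deg)) +
    ggplot2::theme_minimal()
  p + ggplot2::annotate("point", x = sol$x_target, y = sol$z_target,
                        colour = "forestgreen", size = 3)
}

#' Plot a synthetic trial recording
#'
#' Lumbar angle over time with cue and contact markers.
#'
#' @param object A `reachvr_trial` recording.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.reachvr_trial <- function(object, ...) {
  ev <- trial_events(object)
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$t_s, y = .data$lumbar_deg)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = ev$cue_time, linetype = "dashed") +
    ggplot2::labs(x = "time (s)", y = "lumbar flexion (°)",
                  title = sprintf("%s trial, θ = %g°", ev$game, ev$theta_deg)) +
    ggplot2::theme_minimal()
  if (!is.na(ev$contact_time)) {
    p <- p + ggplot2::geom_vline(xintercept = ev$contact_time,
                                 linetype = "dotted", colour = "forestgreen")
  }
  p
}

#' Outcome means by game and target height
#'
#' Cohort mean with one-standard-deviation error bars per game at each
#' intended target height — the standard display for comparing the three
#' games.
#'
#' @param table Cohort table from [aggregate_trials()].
#' @param outcome Outcome column (unquoted), e.g.
#'   `peak_lumbar_velocity_dps`.
#' @return A ggplot.
#' @export
plot_outcomes <- function(table, outcome) {
  oc <- names(tidyselect::eval_select(rlang::enquo(outcome), table))
  summ <- table |>
    dplyr::group_by(.data$game, .data$theta_deg) |>
    dplyr::summarise(mean = mean(.data[[oc]]), sd = sd(.data[[oc]]),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = factor(.data$theta_deg), y = .data$mean,
                                     fill = .data$game)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           position = ggplot2::position_dodge(0.9), width = 0.25) +
    ggplot2::labs(x = "intended trunk-flexion angle (°)", y = oc,
                  fill = NULL) +
    ggplot2::theme_minimal()
}
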