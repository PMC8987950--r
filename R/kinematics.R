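# Kinematic outcome pipeline.
#
# Joint-angle series are smoothed and differentiated with a 41-point,
# fourth-order Savitzky-Golay filter (central least-squares coefficients,
# mirror-padded boundaries). Outcomes per trial: lumbar flexion excursion
# (peak minus onset within the analysis window), peak lumbar flexion
# velocity, and hand position at contact relative to the feet midpoint. The
# analysis window runs from the movement cue to 200 ms after target contact
# (to the peak of forward hand displacement for misses). Trials with an
# apparent lack of lumbar motion are excluded by a configurable excursion
# threshold; right-hand trials only enter the aggregate.

#' Savitzky-Golay filter specification
#'
#' @param window Odd window length in samples (default 41).
#' @param polyorder Polynomial order (default 4); must be `< window`.
#' @param rate Sampling rate in Hz (default 100); scales the derivative to
#'   units/s.
#' @return A list of class `reachvr_filter_spec`.
#' @export
filter_spec <- function(window = 41, polyorder = 4, rate = 100) {
  if (window %% 2 != 1 || window < 3) abort_validation("`window` must be odd and >= 3")
  if (polyorder >= window) abort_validation("`polyorder` must be smaller than `window`")
  if (rate <= 0) abort_validation("`rate` must be positive")
  structure(list(window = as.integer(window), polyorder = as.integer(polyorder),
                 rate = rate), class = "reachvr_filter_spec")
}

#' Savitzky-Golay smoothing and differentiation
#'
#' Fits a least-squares polynomial within each sliding window and evaluates
#' it (and its first derivative) at the window centre. Boundaries are
#' handled by mirror padding (reflection about the end samples), so the
#' output has the same length as the input. The derivative is returned in
#' input-units per second.
#'
#' @param x Numeric series (length `>= window`).
#' @param spec A [filter_spec()].
#' @return A list with `smooth` and `deriv`, each the length of `x`.
#' @examples
#' t <- seq(0, 2, by = 0.01)
#' out <- sg_smooth_diff(2 * t^3 - t, filter_spec())
#' max(abs(out$deriv[50:150] - (6 * t[50:150]^2 - 1)))  # ~1e-12
#' @export
sg_smooth_diff <- function(x, spec = filter_spec()) {
  n <- length(x)
  w <- spec$window
  if (n < w) {
    abort_reachvr(sprintf("series of length %d is shorter than the filter window (%d)", n, w),
                  "reachvr_length_error")
  }
  h <- (w - 1L) %/% 2L
  # mirror padding: reflect about the end samples without repeating them
  pad <- c(x[(h + 1L):2L], x, x[(n - 1L):(n - h)])
  c0 <- signal::sgolay(p = spec$polyorder, n = w, m = 0)[h + 1L, ]
  c1 <- signal::sgolay(p = spec$polyorder, n = w, m = 1, ts = 1 / spec$rate)[h + 1L, ]
  sm <- stats::filter(pad, rev(c0), sides = 2)
  dv <- stats::filter(pad, rev(c1), sides = 2)
  idx <- (h + 1L):(h + n)
  list(smooth = as.numeric(sm[idx]), deriv = as.numeric(dv[idx]))
}

#' Analysis window of a trial
#'
#' The window opens at the movement cue (target appears, opponent winds up,
#' fish starts swimming) and closes 200 ms after target contact. For missed
#' trials with an attempted reach the window closes at the peak of forward
#' hand displacement. Both ends are clipped to the recording.
#'
#' @param rec A `reachvr_trial` recording.
#' @return Named numeric `c(t_start, t_end)` in seconds.
#' @export
analysis_window <- function(rec) {
  ev <- trial_events(rec)
  if (is.null(ev) || is.null(ev$cue_time) || is.na(ev$cue_time)) {
    abort_reachvr("recording has no cue event; cannot window the trial",
                  "reachvr_invalid_trial_error")
  }
  t_end <- if (!is.na(ev$contact_time)) {
    ev$contact_time + 0.200
  } else {
    rec$t_s[which.max(rec$hand_x_m)]
  }
  c(t_start = max(ev$cue_time, rec$t_s[1]),
    t_end = min(t_end, tail(rec$t_s, 1)))
}

#' Outcome metrics for one trial
#'
#' Smooths and differentiates the lumbar series, restricts to the analysis
#' window, and extracts lumbar flexion excursion, peak lumbar flexion
#' velocity and the hand position at contact (relative to the feet-midpoint
#' origin). Excursion is peak-minus-onset by default (`mode = "peak"`);
#' `mode = "net"` gives the end-minus-start change instead.
#'
#' @param rec A `reachvr_trial` recording.
#' @param spec A [filter_spec()].
#' @param mode Excursion definition, `"peak"` (default) or `"net"`.
#' @return A one-row tibble: `lumbar_excursion_deg`,
#'   `peak_lumbar_velocity_dps`, `impact_ap_m`, `impact_vertical_m`,
#'   `missed`.
#' @export
compute_metrics <- function(rec, spec = filter_spec(), mode = c("peak", "net")) {
  mode <- match.arg(mode)
  ev <- trial_events(rec)
  win <- analysis_window(rec)
  f <- sg_smooth_diff(rec$lumbar_deg, spec)
  in_win <- rec$t_s >= win[["t_start"]] & rec$t_s <= win[["t_end"]]
  sm <- f$smooth[in_win]
  excursion <- switch(mode,
                      peak = max(sm) - sm[1],
                      net = tail(sm, 1) - sm[1])
  peak_vel <- max(f$deriv[in_win])
  if (!is.na(ev$contact_time)) {
    ci <- which.min(abs(rec$t_s - ev$contact_time))
    impact_ap <- rec$hand_x_m[ci]
    impact_v <- rec$hand_z_m[ci]
  } else {
    impact_ap <- NA_real_
    impact_v <- NA_real_
  }
  tibble::tibble(
    lumbar_excursion_deg = excursion,
    peak_lumbar_velocity_dps = peak_vel,
    impact_ap_m = impact_ap,
    impact_vertical_m = impact_v,
    missed = is.na(ev$contact_time))
}

#' Screen a trial for apparent lack of lumbar motion
#'
#' Automated surrogate for the study team's visual review: a trial is
#' excluded when its lumbar excursion falls below `min_excursion` degrees.
#' Misses are retained as long as the participant reacted (i.e. produced at
#' least that much lumbar motion).
#'
#' @param metrics A metrics row/tibble from [compute_metrics()].
#' @param min_excursion Exclusion threshold, degrees (default 2).
#' @return Logical vector: `TRUE` when the trial is included.
#' @export
screen_trial <- function(metrics, min_excursion = 2.0) {
  metrics$lumbar_excursion_deg >= min_excursion
}

#' Per-trial metrics for a synthesised cohort
#'
#' Maps [compute_metrics()] over the `recording` list-column of a cohort
#' tibble and applies the exclusion screen.
#'
#' @param trials Cohort tibble from [synthesize_cohort()].
#' @param spec A [filter_spec()].
#' @param min_excursion Exclusion threshold, degrees.
#' @param mode Excursion definition, see [compute_metrics()].
#' @return The cohort tibble without recordings, with metric columns plus
#'   `included` and `exclusion_reason`.
#' @export
trial_metrics <- function(trials, spec = filter_spec(), min_excursion = 2.0,
                          mode = "peak") {
  m <- purrr::map_dfr(trials$recording, compute_metrics, spec = spec, mode = mode)
  out <- dplyr::bind_cols(dplyr::select(trials, -"recording"), m)
  out$included <- screen_trial(out, min_excursion)
  out$exclusion_reason <- ifelse(out$included, NA_character_, "lack_of_lumbar_motion")
  out
}

#' Aggregate trial metrics into the participant x game x height table
#'
#' Keeps included right-hand trials only (fishing and dodging are played
#' with the right hand; left-hand reaching trials are dropped), then
#' averages every outcome within each participant x game x target-height
#' cell. Cells missing from the complete design are reported in the
#' `incomplete` attribute (the repeated-measures ANOVA needs a complete
#' design).
#'
#' @param metrics Per-trial metrics from [trial_metrics()].
#' @return A tibble with one row per (participant, game, theta_deg) cell:
#'   `n_trials` and the mean of each outcome. Attribute `incomplete` lists
#'   expected-but-missing cells.
#' @export
aggregate_trials <- function(metrics) {
  kept <- dplyr::filter(metrics, .data$included,
                        is.na(.data$hand) | .data$hand == "right")
  tab <- kept |>
    dplyr::group_by(.data$participant, .data$game, .data$theta_deg) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      lumbar_excursion_deg = mean(.data$lumbar_excursion_deg),
      peak_lumbar_velocity_dps = mean(.data$peak_lumbar_velocity_dps),
      impact_ap_m = mean(.data$impact_ap_m, na.rm = TRUE),
      impact_vertical_m = mean(.data$impact_vertical_m, na.rm = TRUE),
      .groups = "drop")
  grid <- tidyr::expand_grid(
    participant = unique(metrics$participant),
    game = intersect(GAMES, unique(metrics$game)),
    theta_deg = sort(unique(metrics$theta_deg[!is.na(metrics$theta_deg)])))
  missing_cells <- dplyr::anti_join(
    grid, tab, by = c("participant", "game", "theta_deg"))
  attr(tab, "incomplete") <- missing_cells
  tab
}
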