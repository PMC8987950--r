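# Suite configuration.

#' Default suite configuration
#'
#' One list that parameterises the whole pipeline: anthropometric sampling
#' distributions for the synthetic cohort, the four target-height angles,
#' launch geometry for the two launch games, generator timing/noise, the
#' Savitzky-Golay filter, the trial-exclusion threshold and the significance
#' level. All values are overridable; `read_config()` merges a YAML or JSON
#' file over these defaults and validates the result.
#'
#' @return A named list of class `reachvr_config`.
#' @export
default_config <- function() {
  structure(list(
    # cohort anthropometrics (m); roughly a 1.72 m adult cohort
    anthro_mean = list(hip_height = 0.93, trunk_length = 0.47, arm_length = 0.62),
    anthro_sd   = list(hip_height = 0.05, trunk_length = 0.03, arm_length = 0.04),
    thetas = c(15, 30, 45, 60),
    # launch geometry (not reported for the deployed games; configurable)
    dodge_site = c(3.0, 1.6), dodge_v0 = 8.0, dodge_windup = 0.5,
    fish_site  = c(2.5, 0.0), fish_apex = 2.0, fish_windup = 0.8,
    g = 9.81,
    # generator behaviour
    movement_time = 1.1,
    speed_gain = c(reachality = 0.8, fishality = 1.0, dodgeality = 1.8),
    speed_sd_log = 0.12, share_sd = 0.06,
    reaction_mean = 0.35, reaction_sd = 0.05,
    noise_sd = 0.3, contact_radius = 0.05,
    cue_time = 0.5, tail_s = 0.5, rate = 100,
    # analysis
    filter_window = 41, filter_order = 4,
    min_excursion = 2.0, alpha = 0.05
  ), class = "reachvr_config")
}

#' Read and validate a configuration file
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON (`.json`) file whose keys
#'   override [default_config()].
#' @return A validated `reachvr_config` list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  user <- switch(ext,
                 yml = , yaml = yaml::read_yaml(path),
                 json = jsonlite::read_json(path, simplifyVector = TRUE),
                 abort_parse(sprintf("unsupported config extension '.%s' (use yaml or json)", ext)))
  cfg <- modifyList(unclass(default_config()), as.list(user))
  cfg$speed_gain <- unlist(cfg$speed_gain)
  cfg$thetas <- as.numeric(cfg$thetas)
  validate_config(structure(cfg, class = "reachvr_config"))
}

#' Validate a suite configuration
#'
#' Checks every field against the preconditions of the module it feeds
#' (positive lengths and speeds, feasible apex, odd filter window longer
#' than the polynomial order, ...).
#'
#' @param cfg A configuration list.
#' @return `cfg`, invisibly classed, or an error describing the violation.
#' @export
validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (any(unlist(cfg$anthro_mean) <= 0) || any(unlist(cfg$anthro_sd) < 0)) {
    abort_validation("anthropometric means must be positive and sds non-negative")
  }
  if (length(cfg$thetas) < 1 || any(diff(cfg$thetas) <= 0) ||
      any(cfg$thetas < 0 | cfg$thetas >= 90)) {
    abort_validation("`thetas` must be strictly increasing angles in [0, 90)")
  }
  if (cfg$dodge_v0 <= 0) abort_validation("`dodge_v0` must be positive")
  if (cfg$g <= 0) abort_validation("`g` must be positive")
  if (cfg$fish_apex <= cfg$fish_site[2]) {
    abort_validation("`fish_apex` must exceed the fish release height")
  }
  if (cfg$movement_time <= 0 || any(cfg$speed_gain <= 0)) {
    abort_validation("movement time and speed gains must be positive")
  }
  if (!all(GAMES %in% names(cfg$speed_gain))) {
    abort_validation("`speed_gain` needs one entry per game")
  }
  if (cfg$filter_window %% 2 != 1 || cfg$filter_order >= cfg$filter_window) {
    abort_validation("filter window must be odd and longer than the polynomial order")
  }
  if (cfg$rate <= 0 || cfg$noise_sd < 0 || cfg$min_excursion < 0 ||
      cfg$alpha <= 0 || cfg$alpha >= 1) {
    abort_validation("rate must be positive, noise/min_excursion non-negative, alpha in (0, 1)")
  }
  invisible(structure(cfg, class = "reachvr_config"))
}
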