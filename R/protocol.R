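# Session protocol scheduling.
#
# The session order is fixed: Reachality, then Fishality, then Dodgeality.
# Reachality is fully deterministic (highest target first, 5 right-hand then
# 5 left-hand reaches per height). The two launch games each run 2 sets of 15
# launches with an exactly balanced, seeded-random mix of the 4 target
# heights and ducking (15 / 5 categories = 3 of each per set).

GAMES <- c("reachality", "fishality", "dodgeality")
DEFAULT_THETAS <- c(15, 30, 45, 60)

#' Reachality trial plan
#'
#' Fixed-order reaching block: the four target heights are presented from
#' highest to lowest (trunk-flexion angle 15 to 60 degrees), with 5
#' right-hand reaches then 5 left-hand reaches at each height. Short rests
#' separate reaches and a long rest separates heights.
#'
#' @param thetas Trunk-flexion angles in presentation order (default
#'   `c(15, 30, 45, 60)`, i.e. highest target first).
#' @param reaches_per_hand Reaches per hand per height (default 5).
#' @param rest_reach_s,rest_height_s Rest after a reach / after the last
#'   reach at a height, seconds (defaults 15 and 120).
#'
#' @return A tibble of plan items: `game`, `event_kind`, `theta_deg`, `hand`,
#'   `set_index` (height block), `trial_index` (within block), `rest_after_s`,
#'   `duck_cue`.
#' @examples
#' nrow(plan_reachality())  # 40 reaches
#' @export
plan_reachality <- function(thetas = DEFAULT_THETAS, reaches_per_hand = 5,
                            rest_reach_s = 15, rest_height_s = 120) {
  blocks <- purrr::imap_dfr(thetas, function(theta, block) {
    n <- 2L * reaches_per_hand
    tibble::tibble(
      game = "reachality",
      event_kind = "reach",
      theta_deg = theta,
      hand = rep(c("right", "left"), each = reaches_per_hand),
      set_index = block,
      trial_index = seq_len(n),
      rest_after_s = c(rep(rest_reach_s, n - 1L), rest_height_s),
      duck_cue = NA_character_
    )
  })
  blocks$rest_after_s[nrow(blocks)] <- 0
  blocks
}

#' Launch-game trial plan (Fishality or Dodgeality)
#'
#' Two sets of 15 launches. Within each set the 5 event categories (the four
#' target heights plus a duck) each occur exactly 3 times, in a uniformly
#' random order drawn from a seeded RNG, so the same seed always reproduces
#' the same plan. Duck items carry only an audio/visual cue tag (a jumping
#' shark in Fishality; a quack and a black ball in Dodgeality) and no target
#' height.
#'
#' @param game `"fishality"` or `"dodgeality"`.
#' @param seed Integer RNG seed for the within-set shuffles.
#' @param thetas Target-height angles (default `c(15, 30, 45, 60)`).
#' @param sets,per_set Number of sets and launches per set (defaults 2, 15;
#'   `per_set` must be a multiple of `length(thetas) + 1`).
#' @param rest_launch_s Pause between launches, seconds (not reported in the
#'   protocol; configurable, default 10).
#'
#' @return A tibble of plan items (columns as [plan_reachality()]); launch
#'   items have `event_kind = "launch"`, ducks `event_kind = "duck"` and a
#'   missing `theta_deg`. Fishality launches are caught with the right hand.
#' @examples
#' p <- plan_launch_game("fishality", seed = 1)
#' table(p$theta_deg, useNA = "ifany")  # 6 of each height + 6 ducks
#' @export
plan_launch_game <- function(game, seed, thetas = DEFAULT_THETAS,
                             sets = 2, per_set = 15, rest_launch_s = 10) {
  game <- match.arg(game, c("fishality", "dodgeality"))
  n_cat <- length(thetas) + 1L
  if (per_set %% n_cat != 0L) {
    abort_validation(sprintf(
      "`per_set` = %d cannot be balanced across %d categories (4 heights + duck)",
      per_set, n_cat))
  }
  per_cat <- per_set %/% n_cat
  duck_cue <- switch(game, fishality = "shark_jump", dodgeality = "quack_black_ball")
  withr::with_seed(as.integer(seed), {
    purrr::map_dfr(seq_len(sets), function(set) {
      cats <- rep(c(thetas, NA_real_), each = per_cat)
      cats <- cats[sample.int(length(cats))]
      tibble::tibble(
        game = game,
        event_kind = ifelse(is.na(cats), "duck", "launch"),
        theta_deg = cats,
        hand = ifelse(is.na(cats), NA_character_, "right"),
        set_index = set,
        trial_index = seq_along(cats),
        rest_after_s = rest_launch_s,
        duck_cue = ifelse(is.na(cats), duck_cue, NA_character_)
      )
    })
  })
}

#' Full-session trial plan
#'
#' Concatenates the three games in the fixed protocol order (Reachality,
#' Fishality, Dodgeality), deriving independent sub-seeds for the two launch
#' games from the master seed.
#'
#' @param seed Master integer seed.
#' @param thetas Target-height angles shared by all games.
#' @return A tibble of plan items with an extra `item` row counter.
#' @examples
#' plan <- plan_session(seed = 42)
#' table(plan$game)
#' @export
plan_session <- function(seed, thetas = DEFAULT_THETAS) {
  sub <- derive_seeds(seed, 2)
  out <- dplyr::bind_rows(
    plan_reachality(thetas = thetas),
    plan_launch_game("fishality", seed = sub[[1]], thetas = thetas),
    plan_launch_game("dodgeality", seed = sub[[2]], thetas = thetas)
  )
  out$item <- seq_len(nrow(out))
  out
}
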