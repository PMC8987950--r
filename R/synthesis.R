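# Synthetic motion generator.
#
# Stands in for the study's motion-capture recordings: for every planned
# trial it produces a 100 Hz time series of sagittal lumbar angle and hand
# position with cue/contact event markers. The body is a planar 2-DoF lumped
# chain (lumbar + hip/lower-limb) pivoting about the hip: the total trunk
# reorientation needed to bring the hand to the intercept point is split
# between the lumbar joint (fraction `lumbar_share`, the quantity of
# interest downstream) and a lumped hip/lower-limb angle. All joint motion
# follows the canonical minimum-jerk profile
#   s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5,
# whose peak rate is 1.875 * amplitude / duration.

#' Minimum-jerk position profile
#'
#' @param tau Normalised time; clamped to `[0, 1]`.
#' @return `s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5`.
#' @export
min_jerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

#' Participant model for motion synthesis
#'
#' Captures the between-participant quantities the generator varies: segment
#' lengths, how much of the required trunk reorientation is produced at the
#' lumbar joint versus hips/lower limbs, reaction and movement times, a
#' per-game speed gain, and angle measurement noise.
#'
#' @param anthro An [anthropometry()] object.
#' @param lumbar_share Fraction in `[0, 1]` of the required reorientation
#'   produced at the lumbar joint. Either a single number or a strategy
#'   tibble with columns `game`, `theta_deg`, `share` (height- and
#'   game-dependent strategies; see [default_share_strategy()]).
#' @param reaction_time Cue-to-movement-onset latency, s.
#' @param movement_time Base reach duration, s (divided by the game's
#'   `speed_gain`).
#' @param speed_gain Named multiplier per game; larger is faster. Defaults
#'   encode the protocol's pacing: dodgeball fastest, self-paced reaching
#'   slowest.
#' @param noise_sd Additive i.i.d. Gaussian measurement noise on angle
#'   samples, degrees.
#' @param reach_envelope Maximum hand-to-shoulder distance counted as
#'   reachable, m; defaults to `1.02 * arm_length` and may not exceed
#'   `1.05 * arm_length`.
#'
#' @return A list of class `reachvr_participant`.
#' @export
participant_model <- function(anthro,
                              lumbar_share = 0.6,
                              reaction_time = 0.35,
                              movement_time = 1.1,
                              speed_gain = c(reachality = 0.8, fishality = 1.0,
                                             dodgeality = 1.8),
                              noise_sd = 0.3,
                              reach_envelope = NULL) {
  anthro <- as_anthro(anthro)
  if (is.numeric(lumbar_share)) {
    if (length(lumbar_share) != 1L || lumbar_share < 0 || lumbar_share > 1) {
      abort_validation("scalar `lumbar_share` must be a single fraction in [0, 1]")
    }
  } else if (is.data.frame(lumbar_share)) {
    if (!all(c("game", "theta_deg", "share") %in% names(lumbar_share)) ||
        any(lumbar_share$share < 0 | lumbar_share$share > 1)) {
      abort_validation("strategy `lumbar_share` needs columns game, theta_deg, share with share in [0, 1]")
    }
  } else {
    abort_validation("`lumbar_share` must be a fraction or a strategy data frame")
  }
  if (movement_time <= 0) abort_validation("`movement_time` must be positive")
  if (noise_sd < 0) abort_validation("`noise_sd` must be >= 0")
  reach_envelope <- reach_envelope %||% (1.02 * anthro$arm_length)
  if (reach_envelope > 1.05 * anthro$arm_length) {
    abort_validation("`reach_envelope` may not exceed 1.05 * arm_length")
  }
  structure(list(anthro = anthro, lumbar_share = lumbar_share,
                 reaction_time = reaction_time, movement_time = movement_time,
                 speed_gain = speed_gain, noise_sd = noise_sd,
                 reach_envelope = reach_envelope),
            class = "reachvr_participant")
}

share_for <- function(participant, game, theta) {
  ls <- participant$lumbar_share
  if (is.numeric(ls)) return(ls)
  hit <- ls$share[ls$game == game & ls$theta_deg == theta]
  if (length(hit) != 1L) {
    abort_validation(sprintf("no lumbar-share strategy entry for game %s, theta %g", game, theta))
  }
  hit
}

#' Default height- and game-dependent lumbar-share strategy
#'
#' Encodes the qualitative redundancy-resolution behaviour observed across
#' the three games: during self-paced reaching, lumbar contribution grows
#' steeply as the target drops; during the fast dodgeball game participants
#' recruit the lumbar spine heavily even for high targets (they start moving
#' down before resolving the incoming ball); the fish game sits in between.
#'
#' @param thetas Target-height angles.
#' @return A tibble with columns `game`, `theta_deg`, `share`.
#' @export
default_share_strategy <- function(thetas = DEFAULT_THETAS) {
  tibble::tibble(
    game = rep(GAMES, each = length(thetas)),
    theta_deg = rep(thetas, times = length(GAMES)),
    share = c(0.30, 0.45, 0.60, 0.80,   # reachality
              0.45, 0.50, 0.60, 0.65,   # fishality
              0.60, 0.62, 0.65, 0.68)   # dodgeality
  )
}

#' Choose where to intercept a launched projectile
#'
#' Players may intercept a launched object anywhere along its flight. Two
#' policies are supported: `"earliest_reachable"` takes the first trajectory
#' sample, at or after the participant's ready time, whose distance from the
#' posture-matched shoulder position is within the reach envelope;
#' `"closest_to_intended"` takes the qualifying sample closest to the
#' intended target point. Returns `NULL` when no sample qualifies (a missed
#' trial, which is a valid outcome).
#'
#' @param traj A `reachvr_trajectory` (times relative to launch).
#' @param participant A [participant_model()].
#' @param policy `"earliest_reachable"` or `"closest_to_intended"`.
#' @param launch_time Global time of the first trajectory sample, s.
#' @param t_earliest Earliest admissible global intercept time (typically
#'   `cue_time + reaction_time`), s.
#' @param intended Intended target point `c(x, z)` (required for
#'   `"closest_to_intended"`).
#'
#' @return A list with `t` (global time), `x`, `z`, or `NULL` on a miss.
#' @export
choose_intercept <- function(traj, participant,
                             policy = c("earliest_reachable", "closest_to_intended"),
                             launch_time = 0, t_earliest = 0, intended = NULL) {
  policy <- match.arg(policy)
  if (nrow(traj) == 0L) abort_validation("empty trajectory")
  anthro <- participant$anthro
  t_glob <- traj$t_s + launch_time
  # posture-matched shoulder for each candidate point
  phi <- vapply(seq_len(nrow(traj)), function(i) {
    required_trunk_angle(anthro, c(traj$x_m[i], traj$z_m[i]))
  }, numeric(1))
  sx <- anthro$trunk_length * sin(deg2rad(phi))
  sz <- anthro$hip_height + anthro$trunk_length * cos(deg2rad(phi))
  dist <- sqrt((traj$x_m - sx)^2 + (traj$z_m - sz)^2)
  ok <- dist <= participant$reach_envelope & t_glob >= t_earliest
  if (!any(ok)) return(NULL)
  idx <- if (policy == "earliest_reachable") {
    which(ok)[1]
  } else {
    if (is.null(intended)) abort_validation("`intended` is required for closest_to_intended")
    cand <- which(ok)
    cand[which.min((traj$x_m[cand] - intended[[1]])^2 +
                     (traj$z_m[cand] - intended[[2]])^2)]
  }
  list(t = t_glob[idx], x = traj$x_m[idx], z = traj$z_m[idx])
}

#' Synthesise one trial recording
#'
#' Produces a mocap-style recording for a planned reach or launch trial: the
#' participant stands upright until the cue, starts moving after the
#' reaction latency, and reorients trunk + arm with minimum-jerk timing so
#' the hand arrives at the intercept point. The lumbar angle rises to
#' `lumbar_share` of the required reorientation; the remainder is absorbed
#' by the lumped hip/lower-limb joint (not recorded). Gaussian measurement
#' noise is added to the lumbar angle.
#'
#' @param plan_item One row of a session plan (`event_kind` `"reach"` or
#'   `"launch"`; ducks are not synthesised).
#' @param participant A [participant_model()].
#' @param target Intended target point (`c(x, z)` or target-set row).
#' @param solution Launch solution for launch trials (ignored for reaches).
#' @param seed Integer seed for the measurement noise.
#' @param rate Sampling rate, Hz (default 100).
#' @param cue_time Time of the game cue (target appears / opponent winds up /
#'   fish starts swimming), s into the recording.
#' @param windup_s Cue-to-launch delay for launch trials, s.
#' @param policy Intercept policy, see [choose_intercept()].
#' @param contact_radius Hand-to-object distance counted as contact, m.
#' @param tail_s Recording kept after the action ends, s.
#'
#' @return A tibble of class `reachvr_trial` with columns `t_s`,
#'   `lumbar_deg`, `hand_x_m`, `hand_z_m` and attribute `events` (cue_time,
#'   launch_time, contact_time, intercept, labels, rate). Missed launches
#'   have `contact_time = NA`.
#' @export
synthesize_trial <- function(plan_item, participant, target, solution = NULL,
                             seed = 1L, rate = 100, cue_time = 0.5,
                             windup_s = 0.8,
                             policy = c("earliest_reachable", "closest_to_intended"),
                             contact_radius = 0.05, tail_s = 0.5) {
  policy <- match.arg(policy)
  kind <- plan_item$event_kind
  if (!kind %in% c("reach", "launch")) {
    abort_validation("only reach and launch items are synthesised (ducks carry no kinematics)")
  }
  anthro <- participant$anthro
  game <- plan_item$game
  p_int <- as_point(target)
  gain <- unname(participant$speed_gain[[game]])
  t0 <- cue_time + participant$reaction_time
  T_nom <- participant$movement_time / gain

  launch_time <- NA_real_
  traj <- NULL
  if (kind == "launch") {
    launch_time <- cue_time + windup_s
    traj <- simulate_flight(solution, dt = 1 / rate)
    hit <- choose_intercept(traj, participant, policy,
                            launch_time = launch_time, t_earliest = t0,
                            intended = p_int)
    if (is.null(hit)) {
      # unreachable flight: participant still reacts toward the intended point
      hit <- list(t = launch_time + tail(traj$t_s, 1), x = p_int[[1]], z = p_int[[2]])
      reachable <- FALSE
    } else reachable <- TRUE
    p_hit <- c(hit$x, hit$z)
    # arrive slightly before the object so the hand is in place to block/catch
    T_mov <- min(T_nom, max(hit$t - t0 - 0.08, 0.25))
    t_end <- max(t0 + T_mov, launch_time + tail(traj$t_s, 1)) + tail_s
  } else {
    p_hit <- p_int
    reachable <- TRUE
    T_mov <- T_nom
    t_end <- t0 + T_mov + tail_s
  }

  t <- seq(0, t_end, by = 1 / rate)
  s <- min_jerk((t - t0) / T_mov)

  theta_req <- required_trunk_angle(anthro, p_hit)
  share <- share_for(participant, game, plan_item$theta_deg)
  lumbar <- share * theta_req * s

  hand_rest <- c(anthro$arm_length, anthro$hip_height + anthro$trunk_length)
  hand_x <- hand_rest[1] + (p_hit[1] - hand_rest[1]) * s
  hand_z <- hand_rest[2] + (p_hit[2] - hand_rest[2]) * s

  # contact = closest approach between hand and target/object, provided it
  # comes within the contact radius (otherwise a miss)
  contact_time <- NA_real_
  if (kind == "reach") {
    d <- sqrt((hand_x - p_hit[1])^2 + (hand_z - p_hit[2])^2)
    i <- which.min(d)
    if (d[i] <= contact_radius) contact_time <- t[i]
  } else if (reachable) {
    # closest approach can fall between recording samples (the ball covers
    # several cm per sample), so evaluate both closed-form paths on a finer
    # grid over the flight
    tf <- seq(launch_time, launch_time + tail(traj$t_s, 1), by = 1 / (10 * rate))
    sf <- min_jerk((tf - t0) / T_mov)
    hx <- hand_rest[1] + (p_hit[1] - hand_rest[1]) * sf
    hz <- hand_rest[2] + (p_hit[2] - hand_rest[2]) * sf
    tb <- tf - launch_time
    bx <- solution$x0 + solution$vx0 * tb
    bz <- solution$z0 + solution$vz0 * tb - 0.5 * solution$g * tb^2
    d <- sqrt((hx - bx)^2 + (hz - bz)^2)
    i <- which.min(d)
    if (d[i] <= contact_radius) contact_time <- tf[i]
  }

  if (participant$noise_sd > 0) {
    lumbar <- lumbar + withr::with_seed(as.integer(seed),
                                        rnorm(length(lumbar), 0, participant$noise_sd))
  }

  out <- tibble::tibble(t_s = t, lumbar_deg = lumbar,
                        hand_x_m = hand_x, hand_z_m = hand_z)
  structure(out, class = c("reachvr_trial", class(out)),
            events = list(
              cue_time = cue_time, launch_time = launch_time,
              contact_time = contact_time,
              intercept = c(x = p_hit[[1]], z = p_hit[[2]]),
              intended = c(x = p_int[[1]], z = p_int[[2]]),
              theta_required = theta_req,
              game = game, theta_deg = plan_item$theta_deg,
              hand = plan_item$hand %||% NA_character_,
              rate = rate))
}

trial_events <- function(rec) attr(rec, "events")

#' Synthesise a full cohort of sessions
#'
#' Draws participant anthropometrics and behavioural parameters from the
#' configured distributions, realises the full session plan for each
#' participant (Reachality, then Fishality, then Dodgeality) and synthesises
#' every reach and launch trial. Duck events are scheduled but carry no
#' kinematics and are skipped, matching the analysis scope.
#'
#' @param n_participants Number of participants (default 31, the study
#'   cohort size).
#' @param seed Master integer seed; the same seed reproduces the cohort
#'   bit-for-bit.
#' @param config Suite configuration, see [default_config()].
#'
#' @return A tibble with one row per synthesised trial: `participant`,
#'   `game`, `theta_deg`, `hand`, `set_index`, `trial_index` and a
#'   `recording` list-column of `reachvr_trial` tibbles. The configuration
#'   is attached as attribute `config`.
#' @export
synthesize_cohort <- function(n_participants = 31, seed = 1L,
                              config = default_config()) {
  if (n_participants < 2) abort_validation("need at least 2 participants")
  seeds <- derive_seeds(seed, n_participants)
  cfg <- config
  strategy <- default_share_strategy(cfg$thetas)

  rows <- purrr::map_dfr(seq_len(n_participants), function(i) {
    ps <- derive_seeds(seeds[[i]], 4)
    draws <- withr::with_seed(ps[[1]], {
      list(
        hip   = max(rnorm(1, cfg$anthro_mean$hip_height, cfg$anthro_sd$hip_height), 0.6),
        trunk = max(rnorm(1, cfg$anthro_mean$trunk_length, cfg$anthro_sd$trunk_length), 0.3),
        arm   = max(rnorm(1, cfg$anthro_mean$arm_length, cfg$anthro_sd$arm_length), 0.4),
        speed_mult = exp(rnorm(1, 0, cfg$speed_sd_log)),
        share_shift = rnorm(1, 0, cfg$share_sd),
        reaction = max(rnorm(1, cfg$reaction_mean, cfg$reaction_sd), 0.15)
      )
    })
    anthro <- anthropometry(draws$hip, draws$trunk, draws$arm)
    strat <- strategy
    strat$share <- pmin(pmax(strat$share + draws$share_shift, 0.05), 0.95)
    participant <- participant_model(
      anthro, lumbar_share = strat, reaction_time = draws$reaction,
      movement_time = cfg$movement_time / draws$speed_mult,
      speed_gain = cfg$speed_gain, noise_sd = cfg$noise_sd)

    targets <- compute_target_set(anthro, cfg$thetas)
    sol <- list(
      fishality = lapply(seq_along(cfg$thetas), function(k)
        solve_fixed_apex(launch_site(cfg$fish_site[1], cfg$fish_site[2]),
                         targets[k, ], H = cfg$fish_apex, g = cfg$g)),
      dodgeality = lapply(seq_along(cfg$thetas), function(k)
        solve_fixed_speed(launch_site(cfg$dodge_site[1], cfg$dodge_site[2]),
                          targets[k, ], v0 = cfg$dodge_v0, g = cfg$g))
    )

    plan <- plan_session(ps[[2]], thetas = cfg$thetas)
    plan <- plan[plan$event_kind != "duck", ]
    trial_seeds <- derive_seeds(ps[[3]], nrow(plan))

    recs <- purrr::map(seq_len(nrow(plan)), function(j) {
      item <- plan[j, ]
      k <- match(item$theta_deg, cfg$thetas)
      synthesize_trial(
        item, participant,
        target = targets[k, ],
        solution = if (item$event_kind == "launch") sol[[item$game]][[k]],
        seed = trial_seeds[[j]], rate = cfg$rate, cue_time = cfg$cue_time,
        windup_s = if (item$game == "dodgeality") cfg$dodge_windup else cfg$fish_windup,
        policy = if (item$game == "dodgeality") "closest_to_intended" else "earliest_reachable",
        contact_radius = cfg$contact_radius, tail_s = cfg$tail_s)
    })

    tibble::tibble(
      participant = sprintf("P%02d", i),
      game = plan$game, theta_deg = plan$theta_deg, hand = plan$hand,
      set_index = plan$set_index, trial_index = plan$trial_index,
      recording = recs)
  })
  attr(rows, "config") <- cfg
  rows
}
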