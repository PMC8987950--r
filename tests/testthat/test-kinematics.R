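make_rec <- function(t, lumbar, hand_x = rep(0, length(t)),
                     hand_z = rep(1, length(t)), cue = 0, contact = NA_real_) {
  structure(tibble::tibble(t_s = t, lumbar_deg = lumbar,
                           hand_x_m = hand_x, hand_z_m = hand_z),
            class = c("reachvr_trial", "tbl_df", "tbl", "data.frame"),
            events = list(cue_time = cue, launch_time = NA_real_,
                          contact_time = contact, game = "reachality",
                          theta_deg = 30, hand = "right", rate = 100))
}

test_that("the Savitzky-Golay filter reproduces polynomials and their derivatives", {
  t <- seq(0, 2, by = 0.01)
  spec <- filter_spec()
  out <- sg_smooth_diff(2 * t^3 - t, spec)
  interior <- 30:170
  expect_lt(max(abs(out$smooth[interior] - (2 * t[interior]^3 - t[interior]))), 1e-8)
  expect_lt(max(abs(out$deriv[interior] - (6 * t[interior]^2 - 1))), 1e-8)

  cst <- sg_smooth_diff(rep(3.5, 100), spec)
  expect_true(all(abs(cst$smooth - 3.5) < 1e-12))
  expect_true(all(abs(cst$deriv) < 1e-10))
})

test_that("a 1 Hz sine sampled at 100 Hz differentiates to within 1%", {
  t <- seq(0, 3, by = 0.01)
  out <- sg_smooth_diff(sin(2 * pi * t), filter_spec())
  want <- 2 * pi * cos(2 * pi * t)
  interior <- 25:(length(t) - 25)
  expect_lt(max(abs(out$deriv[interior] - want[interior])) / max(abs(want)), 0.01)
})

test_that("series shorter than the window raise a length error", {
  expect_error(sg_smooth_diff(rnorm(40), filter_spec(window = 41)),
               class = "reachvr_length_error")
  expect_error(filter_spec(window = 40), class = "reachvr_validation_error")
  expect_error(filter_spec(window = 5, polyorder = 5),
               class = "reachvr_validation_error")
})

test_that("the analysis window spans cue to contact + 200 ms, clipped to the trial", {
  t <- seq(0, 3, by = 0.01)
  rec <- make_rec(t, rep(0, length(t)), cue = 1.0, contact = 1.8)
  expect_equal(unname(analysis_window(rec)), c(1.0, 2.0))
  # contact at the final sample: clipped to the recording end
  rec2 <- make_rec(t, rep(0, length(t)), cue = 1.0, contact = 3.0)
  expect_equal(unname(analysis_window(rec2)), c(1.0, 3.0))
  rec3 <- make_rec(t, rep(0, length(t)), cue = NA_real_)
  expect_error(analysis_window(rec3), class = "reachvr_invalid_trial_error")
})

test_that("missed trials window to the peak of forward hand displacement", {
  t <- seq(0, 3, by = 0.01)
  hand_x <- 0.7 * min_jerk(t / 1.5) - 0.2 * min_jerk((t - 1.5) / 1.5)  # peak then retreat
  rec <- make_rec(t, 30 * min_jerk(t / 1.5), hand_x = hand_x, cue = 0.2)
  win <- analysis_window(rec)
  expect_equal(win[["t_end"]], t[which.max(hand_x)])
  m <- compute_metrics(rec)
  expect_true(m$missed)
  expect_true(is.na(m$impact_ap_m))
})

test_that("excursion and peak velocity are offset-invariant and mode-sensitive", {
  t <- seq(0, 3, by = 0.01)
  ang <- 40 * min_jerk(t - 0.5)   # 1 s rise starting at 0.5 s
  rec <- make_rec(t, ang, cue = 0.2, contact = 1.7)
  rec_off <- make_rec(t, ang + 17.3, cue = 0.2, contact = 1.7)
  m1 <- compute_metrics(rec)
  m2 <- compute_metrics(rec_off)
  expect_equal(m1$lumbar_excursion_deg, m2$lumbar_excursion_deg, tolerance = 1e-9)
  expect_equal(m1$peak_lumbar_velocity_dps, m2$peak_lumbar_velocity_dps, tolerance = 1e-9)
  # flex-then-return trial: peak-minus-onset exceeds net change
  ang_ret <- 40 * min_jerk(t - 0.5) - 25 * min_jerk(t - 1.8)
  rec_ret <- make_rec(t, ang_ret, cue = 0.2, contact = 2.7)
  mp <- compute_metrics(rec_ret, mode = "peak")
  mn <- compute_metrics(rec_ret, mode = "net")
  expect_gt(mp$lumbar_excursion_deg, mn$lumbar_excursion_deg)
})

test_that("screening drops still trials, keeps reacted misses, threshold 0 keeps all", {
  m <- tibble::tibble(lumbar_excursion_deg = c(0.3, 25, 1.9, 2.0), missed = c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(screen_trial(m), c(FALSE, TRUE, FALSE, TRUE))
  expect_true(all(screen_trial(m, min_excursion = 0)))
  # a static posture trial measures ~0 excursion and is excluded
  t <- seq(0, 2, by = 0.01)
  static <- make_rec(t, rep(5, length(t)), cue = 0.2, contact = 1.0)
  ms <- compute_metrics(static)
  expect_lt(ms$lumbar_excursion_deg, 2)
  expect_false(screen_trial(ms))
})

test_that("aggregation keeps right-hand included trials and reports empty cells", {
  base <- tidyr::expand_grid(participant = c("P1", "P2"),
                             game = c("reachality", "fishality", "dodgeality"),
                             theta_deg = c(15, 30, 45, 60),
                             trial_index = 1:5)
  base$hand <- "right"
  base$set_index <- 1L
  base$event_kind <- ifelse(base$game == "reachality", "reach", "launch")
  base$lumbar_excursion_deg <- 10
  base$peak_lumbar_velocity_dps <- 50
  base$impact_ap_m <- 0.7
  base$impact_vertical_m <- 1.0
  base$included <- TRUE
  # add left-hand reaching trials with an outlandish value: must not appear
  left <- base[base$game == "reachality" & base$trial_index == 1, ]
  left$hand <- "left"
  left$lumbar_excursion_deg <- 999
  tab <- aggregate_trials(dplyr::bind_rows(base, left))
  expect_equal(nrow(tab), 2 * 3 * 4)
  expect_true(all(tab$lumbar_excursion_deg == 10))
  expect_true(all(tab$n_trials == 5L))
  expect_equal(nrow(attr(tab, "incomplete")), 0L)

  # excluding every trial of one cell lists it in the completeness report
  drop <- dplyr::bind_rows(base, left)
  drop$included[drop$participant == "P1" & drop$game == "fishality" & drop$theta_deg == 45] <- FALSE
  tab2 <- aggregate_trials(drop)
  inc <- attr(tab2, "incomplete")
  expect_equal(nrow(inc), 1L)
  expect_equal(inc$game, "fishality")
  expect_equal(inc$theta_deg, 45)
})
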