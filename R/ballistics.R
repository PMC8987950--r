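# Inverse ballistic launch solvers and flight sampling.
#
# Projectiles are point masses under gravity alone, so flights are parabolic
# in the midsagittal (x, z) plane. Two inversion modes mirror the two launch
# games: the dodgeball solver keeps launch speed fixed and picks the launch
# angle (low-arc root -> flat, fast trajectory); the fish solver prescribes
# the apex height H and derives both speed and angle, intercepting the target
# on the descending limb of the arc.

#' Projectile release point
#'
#' @param x Anterior position of the release point, m (feet-midpoint frame).
#' @param z Height of the release point, m (must be `>= 0`).
#' @return A named list of class `reachvr_launch_site`.
#' @examples
#' launch_site(3, 1.6)  # virtual opponent's throwing hand
#' @export
launch_site <- function(x, z) {
  if (!is.finite(x) || !is.finite(z) || z < 0) {
    abort_validation("launch site needs finite coordinates with z >= 0")
  }
  structure(list(x = x, z = z), class = "reachvr_launch_site")
}

as_point <- function(target) {
  if (is.numeric(target) && length(target) == 2L) {
    return(c(x = target[[1]], z = target[[2]]))
  }
  if (is.list(target) && all(c("anterior_m", "vertical_m") %in% names(target))) {
    return(c(x = target$anterior_m[[1]], z = target$vertical_m[[1]]))
  }
  abort_validation("`target` must be c(x, z) or a target row with anterior_m/vertical_m")
}

new_launch_solution <- function(mode, site, target, v0, alpha, vx0, vz0,
                                t_flight, g) {
  tibble::tibble(
    mode = mode,
    v0 = v0, alpha_deg = alpha, vx0 = vx0, vz0 = vz0, t_flight = t_flight,
    x0 = site$x, z0 = site$z,
    x_target = target[["x"]], z_target = target[["z"]], g = g
  ) -> out
  class(out) <- c("reachvr_launch_solution", class(out))
  out
}

#' Fixed-speed launch-angle solver (dodgeball mode)
#'
#' Given a release point, an intended intercept location and a fixed launch
#' speed, solves the parabolic flight equation
#' \deqn{\Delta z = R\tan\alpha - \frac{gR^2}{2 v_0^2 \cos^2\alpha}}
#' for the launch angle \eqn{\alpha} and returns the *low-arc* root, i.e. the
#' flat, fast trajectory of the two physical solutions.
#'
#' @param site A [launch_site()].
#' @param target Intended intercept: `c(x, z)` or a row from
#'   [compute_target_set()].
#' @param v0 Launch speed, m/s (`> 0`).
#' @param g Gravitational acceleration, m/s^2 (default 9.81).
#'
#' @return A one-row `reachvr_launch_solution` tibble with `v0`, `alpha_deg`
#'   (signed, above horizontal), velocity components `vx0`/`vz0`, `t_flight`
#'   and the geometry used.
#' @examples
#' # equal heights at maximum range: alpha = 45 degrees exactly
#' solve_fixed_speed(launch_site(0, 1), c(9.81, 1), v0 = 9.81, g = 9.81)
#' @export
solve_fixed_speed <- function(site, target, v0, g = 9.81) {
  target <- as_point(target)
  if (!is.finite(v0) || v0 <= 0) abort_validation("`v0` must be positive")
  if (!is.finite(g) || g <= 0) abort_validation("`g` must be positive")
  R <- abs(target[["x"]] - site$x)
  if (R < 1e-12) {
    abort_reachvr("degenerate geometry: target is vertically above/below the launch site (R = 0)",
                  "reachvr_degenerate_error")
  }
  dz <- target[["z"]] - site$z
  k <- g * R^2 / (2 * v0^2)
  # quadratic in u = tan(alpha): k u^2 - R u + (dz + k) = 0
  disc <- R^2 - 4 * k * (dz + k)
  if (disc < 0) {
    if (disc > -1e-12 * max(R^2, 1)) disc <- 0 else {
      abort_unreachable(sprintf(
        "target unreachable at v0 = %g m/s (speed below minimum for this geometry)", v0))
    }
  }
  u_low <- (R - sqrt(disc)) / (2 * k)   # smaller tan(alpha) -> low/flat arc
  alpha <- atan(u_low)
  vx0 <- sign(target[["x"]] - site$x) * v0 * cos(alpha)
  vz0 <- v0 * sin(alpha)
  t_flight <- R / (v0 * cos(alpha))
  new_launch_solution("fixed_speed_low_arc", site, target, v0,
                      rad2deg(alpha), vx0, vz0, t_flight, g)
}

#' Fixed-apex solver (fish mode)
#'
#' Prescribes the apex height `H` of the parabolic arc and derives launch
#' speed and angle so the projectile passes through the intended intercept on
#' the *descending* limb: \eqn{v_{z0} = \sqrt{2g(H - z_0)}},
#' \eqn{t_{fl} = v_{z0}/g + \sqrt{2(H - z_t)/g}},
#' \eqn{v_{x0} = (x_t - x_0)/t_{fl}}.
#'
#' @inheritParams solve_fixed_speed
#' @param H Apex height of the flight, m; must strictly exceed both the
#'   release height and the intercept height.
#' @return A one-row `reachvr_launch_solution` tibble (mode
#'   `fixed_apex_descending`).
#' @examples
#' solve_fixed_apex(launch_site(2.5, 0), c(0.6, 1.2), H = 2)
#' @export
solve_fixed_apex <- function(site, target, H, g = 9.81) {
  target <- as_point(target)
  if (!is.finite(g) || g <= 0) abort_validation("`g` must be positive")
  if (!is.finite(H) || H <= site$z || H <= target[["z"]]) {
    abort_reachvr(sprintf(
      "infeasible apex: H = %g m must strictly exceed release height (%g m) and intercept height (%g m)",
      H, site$z, target[["z"]]), "reachvr_infeasible_apex_error")
  }
  if (abs(target[["x"]] - site$x) < 1e-12) {
    abort_reachvr("degenerate geometry: zero horizontal separation",
                  "reachvr_degenerate_error")
  }
  vz0 <- sqrt(2 * g * (H - site$z))
  t_flight <- vz0 / g + sqrt(2 * (H - target[["z"]]) / g)
  vx0 <- (target[["x"]] - site$x) / t_flight
  v0 <- sqrt(vx0^2 + vz0^2)
  alpha <- atan2(vz0, abs(vx0))
  new_launch_solution("fixed_apex_descending", site, target, v0,
                      rad2deg(alpha), vx0, vz0, t_flight, g)
}

#' Sample a solved flight as a trajectory
#'
#' Closed-form sampling of the parabola `x(t) = x0 + vx0 t`,
#' `z(t) = z0 + vz0 t - g t^2 / 2` on `[0, t_flight]`; the final sample falls
#' exactly at `t_flight` (appended when the grid does not land on it).
#'
#' @param sol A launch solution from [solve_fixed_speed()] or
#'   [solve_fixed_apex()].
#' @param dt Sampling interval, s (default 0.01, i.e. 100 Hz).
#' @return A tibble of class `reachvr_trajectory` with columns `t_s`, `x_m`,
#'   `z_m`; the solution row is kept as attribute `solution`.
#' @export
simulate_flight <- function(sol, dt = 0.01) {
  if (!is.finite(dt) || dt <= 0) abort_validation("`dt` must be positive")
  t <- seq(0, sol$t_flight, by = dt)
  if (tail(t, 1) < sol$t_flight - 1e-12) t <- c(t, sol$t_flight)
  out <- tibble::tibble(
    t_s = t,
    x_m = sol$x0 + sol$vx0 * t,
    z_m = sol$z0 + sol$vz0 * t - 0.5 * sol$g * t^2
  )
  structure(out, class = c("reachvr_trajectory", class(out)), solution = sol)
}

#' Write a trajectory as TSV
#'
#' Columns `t_s`, `x_m`, `z_m`, tab-separated.
#' @param traj A `reachvr_trajectory` tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(traj, path) {
  readr::write_tsv(tibble::as_tibble(traj)[c("t_s", "x_m", "z_m")], path)
  invisible(path)
}
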