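# Anthropometry-scaled target geometry.
#
# Coordinate frame: origin at the midpoint of the feet on the floor, +x
# anterior, +z up; all motion lies in the midsagittal plane. The hip pivot
# sits on the vertical through the origin at height `hip_height`. In the
# reference posture the trunk is vertical and the arm horizontal forward, so
# the hand sits at (arm_length, hip_height + trunk_length). A target for
# trunk-flexion angle theta is the hand position after trunk + arm rotate
# rigidly (forward) about the hip pivot by theta.

#' Participant anthropometrics
#'
#' Bundles the three segment lengths that scale every target location:
#' hip height (floor to hip pivot), trunk length (hip pivot to shoulder) and
#' arm length (shoulder to hand), all in metres.
#'
#' @param hip_height Floor-to-hip-pivot distance, m.
#' @param trunk_length Hip-pivot-to-shoulder distance, m.
#' @param arm_length Shoulder-to-hand distance, m.
#'
#' @return An object of class `reachvr_anthro`: a named list with the three
#'   lengths.
#' @examples
#' anthropometry(hip_height = 0.95, trunk_length = 0.48, arm_length = 0.72)
#' @export
anthropometry <- function(hip_height, trunk_length, arm_length) {
  lens <- c(hip_height = hip_height, trunk_length = trunk_length,
            arm_length = arm_length)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    abort_validation("all anthropometric segment lengths must be finite and strictly positive")
  }
  structure(as.list(lens), class = "reachvr_anthro")
}

as_anthro <- function(x) {
  if (inherits(x, "reachvr_anthro")) return(x)
  if (is.list(x) || is.data.frame(x)) {
    need <- c("hip_height", "trunk_length", "arm_length")
    if (all(need %in% names(x))) {
      return(anthropometry(x[["hip_height"]][[1]], x[["trunk_length"]][[1]],
                           x[["arm_length"]][[1]]))
    }
  }
  abort_validation("cannot interpret `anthro`: expected anthropometry() or a list/data frame with hip_height, trunk_length, arm_length")
}

#' @export
print.reachvr_anthro <- function(x, ...) {
  cat(sprintf("<anthropometry> hip %.3f m | trunk %.3f m | arm %.3f m\n",
              x$hip_height, x$trunk_length, x$arm_length))
  invisible(x)
}

#' Target location for one trunk-flexion angle
#'
#' Computes the point a participant's hand would occupy if trunk and arm
#' rotated rigidly about the hip pivot by `theta` degrees from the reference
#' posture (trunk vertical, arm horizontal forward). Presenting this point as
#' a contact target elicits exactly `theta` degrees of trunk flexion when the
#' participant moves only at the trunk.
#'
#' @param anthro An [anthropometry()] object (or coercible list/row).
#' @param theta Intended trunk-flexion angle, degrees, in `[0, 90)`.
#'
#' @return A one-row tibble with `theta_deg`, `anterior_m` (+x, forward of
#'   the feet midpoint) and `vertical_m` (+z, above the floor).
#' @details With trunk length \eqn{L_t}, arm length \eqn{L_a} and hip height
#'   \eqn{h}: anterior \eqn{= L_t\sin\theta + L_a\cos\theta}, vertical
#'   \eqn{= h + L_t\cos\theta - L_a\sin\theta}. The hand-to-pivot distance
#'   \eqn{\sqrt{L_t^2+L_a^2}} is independent of \eqn{\theta}.
#' @examples
#' a <- anthropometry(1.0, 0.5, 0.7)
#' compute_target(a, 0)   # reference posture: (0.7, 1.5)
#' compute_target(a, 45)
#' @export
compute_target <- function(anthro, theta) {
  anthro <- as_anthro(anthro)
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta)) {
    abort_domain("`theta` must be a single finite number (degrees)")
  }
  if (theta < 0 || theta >= 90) {
    abort_domain(sprintf("`theta` = %g is outside the supported range [0, 90) degrees", theta))
  }
  th <- deg2rad(theta)
  tibble::tibble(
    theta_deg  = theta,
    anterior_m = anthro$trunk_length * sin(th) + anthro$arm_length * cos(th),
    vertical_m = anthro$hip_height + anthro$trunk_length * cos(th) -
      anthro$arm_length * sin(th)
  )
}

#' Full anthropometry-scaled target set
#'
#' One target per configured trunk-flexion angle. With the default angles
#' (15, 30, 45, 60 degrees) this is the four-point ladder shared by all
#' three games; target height decreases strictly with increasing angle.
#'
#' @inheritParams compute_target
#' @param thetas Strictly increasing vector of angles in `[0, 90)` degrees.
#'
#' @return A tibble of class `reachvr_target_set` (columns as
#'   [compute_target()]), with the anthropometry attached as attribute
#'   `anthro`.
#' @examples
#' compute_target_set(anthropometry(0.95, 0.48, 0.72))
#' @export
compute_target_set <- function(anthro, thetas = c(15, 30, 45, 60)) {
  anthro <- as_anthro(anthro)
  if (length(thetas) < 1L || any(diff(thetas) <= 0)) {
    abort_domain("`thetas` must be a strictly increasing vector of angles")
  }
  out <- purrr::map_dfr(thetas, ~ compute_target(anthro, .x))
  structure(out, class = c("reachvr_target_set", class(out)), anthro = anthro)
}

#' Trunk-flexion angle required to point the hand at an arbitrary location
#'
#' Inverse of the rigid trunk+arm rotation model: the flexion angle for which
#' the hand direction from the hip pivot points at `point`. For points on the
#' hand's circular locus this is the exact angle that reaches them; for other
#' points it is the closest-approach angle. Clamped to `[0, 90]` degrees.
#'
#' @inheritParams compute_target
#' @param point Numeric `c(x, z)` in metres (feet-midpoint frame).
#' @return Angle in degrees.
#' @export
required_trunk_angle <- function(anthro, point) {
  anthro <- as_anthro(anthro)
  dx <- point[[1]]
  dz <- point[[2]] - anthro$hip_height
  ref <- atan2(anthro$arm_length, anthro$trunk_length)  # hand bearing at theta = 0
  phi <- rad2deg(atan2(dx, dz) - ref)
  min(max(phi, 0), 90)
}

# Shoulder position for a given trunk-flexion angle (degrees).
shoulder_position <- function(anthro, theta_deg) {
  th <- deg2rad(theta_deg)
  c(x = anthro$trunk_length * sin(th),
    z = anthro$hip_height + anthro$trunk_length * cos(th))
}

#' Write / read a target set as CSV
#'
#' Plain CSV with columns `theta_deg, anterior_m, vertical_m`.
#'
#' @param targets A target-set tibble from [compute_target_set()].
#' @param path File path.
#' @return `write_target_csv()` returns `path` invisibly; `read_target_csv()`
#'   returns a tibble.
#' @export
write_target_csv <- function(targets, path) {
  readr::write_csv(tibble::as_tibble(targets)[c("theta_deg", "anterior_m", "vertical_m")], path)
  invisible(path)
}

#' @rdname write_target_csv
#' @export
read_target_csv <- function(path) {
  check_header(path, c("theta_deg", "anterior_m", "vertical_m"), delim = ",")
  readr::read_csv(path, show_col_types = FALSE)
}
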