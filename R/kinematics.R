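# Per-frame kinematics.  A "step" is the thorax displacement between two
# consecutive video frames; a turning angle is the change in direction
# between two consecutive steps.  Body-axis orientation is the direction
# of the line from the thorax through the head.

#' Step lengths and headings of a trajectory
#'
#' @param traj an [trajectory()] object (>= 2 frames).
#' @return data.frame with `length` (mm) and `heading` (degrees, CCW from
#'   +x) for each of the `n - 1` consecutive-frame thorax displacements.
#'   Zero-length steps have no direction: their heading is `NA`.
#' @export
compute_steps <- function(traj) {
  n <- nrow(traj)
  if (n < 2) stop_insufficient("need at least 2 frames for steps")
  dx <- diff(traj$thorax_x)
  dy <- diff(traj$thorax_y)
  len <- sqrt(dx^2 + dy^2)
  heading <- rad2deg(atan2(dy, dx))
  heading[len == 0] <- NA_real_
  data.frame(length = len, heading = heading)
}

#' Turning angles between consecutive steps
#'
#' The signed change of direction between step i and step i + 1, wrapped
#' to (-180, 180] degrees.  Pairs in which either heading is undefined
#' (a zero-length step) are skipped: the corresponding entry is `NA` and
#' the number of skipped pairs is returned in attribute `n_skipped`.
#'
#' @param headings step headings in degrees (from [compute_steps()]).
#' @return numeric vector of length `length(headings) - 1`.
#' @export
compute_turning_angles <- function(headings) {
  if (length(headings) < 2)
    stop_insufficient("need at least 2 step headings for turning angles")
  turns <- wrap180(diff(headings))
  n_skipped <- sum(is.na(turns))
  if (all(is.na(turns)))
    stop_insufficient("no pair of consecutive defined headings")
  structure(turns, n_skipped = n_skipped)
}

#' Per-step speed, moving flags and a stop-excluded speed summary
#'
#' Speed for step i is the thorax displacement divided by the frame
#' interval.  Frames where the ant is effectively stationary -- speed
#' below `v_stop` -- are excluded from both the distance and the time
#' entering the mean speed, so stopping never dilutes it.
#'
#' @param traj an [trajectory()] object (>= 2 frames).
#' @param v_stop stop threshold in mm/s (default 0.01).
#' @return list with `speed` (mm/s, per step), `moving` (logical, per
#'   step; `moving <=> speed >= v_stop`) and `summary`, a list holding
#'   `mean_speed`, `total_moving_distance`, `total_moving_time`,
#'   `total_duration`, `stopped_time` and `all_stopped`.  When every step
#'   is below threshold, `mean_speed` is `NA` and `all_stopped` is TRUE.
#' @export
compute_speed_series <- function(traj, v_stop = 0.01) {
  if (nrow(traj) < 2) stop_insufficient("need at least 2 frames for speed")
  if (v_stop < 0) stop_format("v_stop must be >= 0")
  steps <- compute_steps(traj)
  dt <- diff(traj$t)
  speed <- steps$length / dt
  moving <- speed >= v_stop
  tm <- sum(dt[moving])
  dist <- sum(steps$length[moving])
  summary <- list(
    mean_speed = if (tm > 0) dist / tm else NA_real_,
    total_moving_distance = dist,
    total_moving_time = tm,
    total_duration = sum(dt),
    stopped_time = sum(dt[!moving]),
    all_stopped = !any(moving))
  list(speed = speed, moving = moving, summary = summary)
}

#' Body-axis orientation per frame
#'
#' The direction of the straight line passing from the thorax coordinates
#' through the head coordinates, in degrees CCW from +x (so a head due
#' "up" of the thorax gives 90).  Frames where head and thorax coincide
#' have no orientation: `NA`, counted in attribute `n_undefined`.  No
#' interpolation is applied.
#'
#' @param traj an [trajectory()] object.
#' @return numeric vector, one orientation per frame.
#' @export
compute_orientation_series <- function(traj) {
  dx <- traj$head_x - traj$thorax_x
  dy <- traj$head_y - traj$thorax_y
  ori <- rad2deg(atan2(dy, dx))
  degen <- dx == 0 & dy == 0
  ori[degen] <- NA_real_
  if (all(degen))
    stop_insufficient("head and thorax coincide in every frame")
  structure(ori, n_undefined = sum(degen))
}

#' Orientation angular velocity
#'
#' The wrapped frame-to-frame change in body-axis orientation divided by
#' the corresponding change in time.  The headline summary is the mean
#' magnitude over defined pairs; the signed mean is reported alongside.
#'
#' @param orientations per-frame orientations in degrees
#'   (from [compute_orientation_series()]).
#' @param times frame times in seconds.
#' @return list with `omega` (deg/s, per consecutive-frame pair; `NA`
#'   where either orientation is undefined), `mean_abs` and `mean_signed`.
#' @export
compute_angular_velocity <- function(orientations, times) {
  if (length(orientations) != length(times))
    stop_format("orientations and times must have equal length")
  if (length(orientations) < 2)
    stop_insufficient("need at least 2 frames for angular velocity")
  omega <- wrap180(diff(orientations)) / diff(times)
  ok <- !is.na(omega)
  if (!any(ok))
    stop_insufficient("no pair of consecutive defined orientations")
  list(omega = omega,
       mean_abs = mean(abs(omega[ok])),
       mean_signed = mean(omega[ok]))
}

#' Full kinematics of a trajectory
#'
#' Convenience wrapper bundling steps, turning angles, speed, orientation
#' and angular velocity for downstream modules.
#'
#' @param traj an [trajectory()] object (>= 3 frames).
#' @param v_stop stop threshold in mm/s passed to
#'   [compute_speed_series()].
#' @return list of class `kinematics_series` with elements `traj`,
#'   `steps`, `turning_angles`, `speed`, `moving`, `speed_summary`,
#'   `orientation`, `angular_velocity`.
#' @export
trajectory_kinematics <- function(traj, v_stop = 0.01) {
  if (nrow(traj) < 3)
    stop_insufficient("need at least 3 frames for full kinematics")
  steps <- compute_steps(traj)
  sp <- compute_speed_series(traj, v_stop = v_stop)
  ori <- compute_orientation_series(traj)
  structure(list(
    traj = traj,
    steps = steps,
    turning_angles = compute_turning_angles(steps$heading),
    speed = sp$speed,
    moving = sp$moving,
    speed_summary = sp$summary,
    orientation = ori,
    angular_velocity = compute_angular_velocity(ori, traj$t)),
    class = "kinematics_series")
}
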