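# Path-straightness indices.  Sinuosity combines the mean step length p,
# the mean cosine c of turning angles and the coefficient of variation b
# of step length:
#
#   S = 2 [ p ( (1 + c) / (1 - c) + b^2 ) ]^(-1/2)
#
# Maximum expected displacement is the asymptotic straightness
#   E^a_max = beta / (1 - beta),  beta = mean cosine of turning angles,
# expressed in units of steps: larger means a straighter path.

.EPS_STRAIGHT <- 1e-9

#' Sinuosity of a path
#'
#' @param steps step lengths in mm (>= 2 values).
#' @param turns turning angles in degrees (>= 1 defined value; `NA`s are
#'   skipped).
#' @param cv_denominator `"population"` (divide by n; default) or
#'   `"sample"` (divide by n - 1) for the step-length CV.
#' @return list with `S` (mm^-1/2), the intermediates `p`, `c`, `b`, and
#'   `flag`: `"ok"`, `"degenerate_straight"` (c at its upper limit; S
#'   returned as 0) or `"perfect_reversal"` (c at its lower limit).
#' @export
sinuosity <- function(steps, turns, cv_denominator = c("population", "sample")) {
  cv_denominator <- match.arg(cv_denominator)
  steps <- steps[!is.na(steps)]
  turns <- turns[!is.na(turns)]
  if (length(steps) < 2) stop_insufficient("need at least 2 step lengths")
  if (length(turns) < 1) stop_insufficient("need at least 1 turning angle")
  p <- mean(steps)
  cc <- mean(cos(deg2rad(turns)))
  sd_steps <- if (cv_denominator == "population") {
    sqrt(mean((steps - p)^2))
  } else {
    stats::sd(steps)
  }
  b <- sd_steps / p
  if (cc >= 1 - .EPS_STRAIGHT)
    return(list(S = 0, p = p, c = cc, b = b, flag = "degenerate_straight"))
  flag <- if (cc <= -1 + .EPS_STRAIGHT) "perfect_reversal" else "ok"
  S <- 2 * (p * ((1 + cc) / (1 - cc) + b^2))^(-0.5)
  list(S = S, p = p, c = cc, b = b, flag = flag)
}

#' Maximum expected displacement of a path
#'
#' @param turns turning angles in degrees (`NA`s skipped).
#' @return list with `e_a_max` (= beta / (1 - beta); `Inf` for an
#'   effectively straight path), `beta`, and `flag` (`"ok"` or
#'   `"straight"`).
#' @export
emax <- function(turns) {
  turns <- turns[!is.na(turns)]
  if (length(turns) < 1) stop_insufficient("need at least 1 turning angle")
  beta <- mean(cos(deg2rad(turns)))
  if (beta >= 1 - .EPS_STRAIGHT)
    return(list(e_a_max = Inf, beta = beta, flag = "straight"))
  list(e_a_max = beta / (1 - beta), beta = beta, flag = "ok")
}

#' Time spent in the recording area
#'
#' Duration from the first to the last frame whose thorax position lies
#' inside the arena rectangle.  Stops are included (this is wall-clock
#' residence time, distinct from the moving time in the speed summary).
#'
#' @param traj an [trajectory()] object.
#' @param arena an [arena_geometry()] object.
#' @return duration in seconds.
#' @export
trip_duration <- function(traj, arena) {
  inside <- traj$thorax_x >= 0 & traj$thorax_x <= arena$width &
    traj$thorax_y >= 0 & traj$thorax_y <= arena$height
  if (!any(inside)) stop_insufficient("no frames inside the arena")
  idx <- which(inside)
  traj$t[idx[length(idx)]] - traj$t[idx[1]]
}

#' Per-ant path metrics
#'
#' One-row summary of a trajectory: mean step length `p`, mean turning
#' cosine `c` (= `beta`), step-length CV `b`, sinuosity `S`, maximum
#' expected displacement `e_a_max`, residence duration, stop-excluded
#' mean speed and mean absolute orientation angular velocity.
#'
#' @param traj an [trajectory()] object.
#' @param arena an [arena_geometry()] object (for residence duration);
#'   `NULL` uses total trajectory duration.
#' @param v_stop stop threshold in mm/s.
#' @param cv_denominator passed to [sinuosity()].
#' @return one-row data.frame.
#' @export
path_metrics <- function(traj, arena = NULL, v_stop = 0.01,
                         cv_denominator = "population") {
  kin <- trajectory_kinematics(traj, v_stop = v_stop)
  sinu <- sinuosity(kin$steps$length, kin$turning_angles,
                    cv_denominator = cv_denominator)
  em <- emax(kin$turning_angles)
  dur <- if (is.null(arena)) {
    max(traj$t) - min(traj$t)
  } else {
    trip_duration(traj, arena)
  }
  data.frame(
    ant_id = attr(traj, "ant_id"),
    condition = attr(traj, "condition"),
    session = attr(traj, "session"),
    p = sinu$p, c = sinu$c, b = sinu$b, S = sinu$S,
    beta = em$beta, e_a_max = em$e_a_max,
    duration = dur,
    mean_speed = kin$speed_summary$mean_speed,
    mean_abs_omega = kin$angular_velocity$mean_abs,
    n_steps = nrow(kin$steps),
    flag = if (sinu$flag != "ok") sinu$flag else em$flag,
    stringsAsFactors = FALSE)
}
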