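# Scanning-bout detection.  A scanning bout is an episode in which the
# ant stops walking and rotates on the spot through successive head
# fixations.  Operationally: a maximal run of sub-threshold steps whose
# thorax stays within r_max of the run's centroid, whose cumulative
# absolute orientation change reaches theta_min, and which lasts at
# least min_dur seconds.  Runs separated by less than gap_merge seconds
# are merged before the criteria are applied.

#' Detect scanning bouts in a trajectory
#'
#' @param traj an [trajectory()] object (>= 3 frames).
#' @param v_stop stop threshold in mm/s (default 0.01, the same as the
#'   speed module's).
#' @param r_max maximum thorax excursion from the bout centroid (mm).
#' @param theta_min minimum cumulative absolute orientation change (deg).
#' @param min_dur minimum bout duration (s).
#' @param gap_merge stopped runs separated by less than this many seconds
#'   are merged into one candidate bout.
#' @return data.frame of class `scan_bouts`, one row per bout ordered by
#'   start time: `start_t`, `end_t`, `duration`, `x`, `y` (mean thorax
#'   position), `total_sweep` (deg), `n_fixations` (direction reversals
#'   of the head sweep + 1).  Zero rows when nothing qualifies.
#' @export
detect_scan_bouts <- function(traj, v_stop = 0.01, r_max = 5,
                              theta_min = 45, min_dur = 0.4,
                              gap_merge = 0.2) {
  empty <- data.frame(start_t = numeric(0), end_t = numeric(0),
                      duration = numeric(0), x = numeric(0), y = numeric(0),
                      total_sweep = numeric(0), n_fixations = integer(0))
  class(empty) <- c("scan_bouts", "data.frame")
  if (nrow(traj) < 3) return(empty)

  sp <- compute_speed_series(traj, v_stop = v_stop)
  ori <- compute_orientation_series(traj)
  stopped <- !sp$moving                      # per step (frame i -> i+1)

  # maximal runs of stopped steps -> frame intervals [first, last]
  r <- rle(stopped)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(s = starts[r$values], e = ends[r$values] + 1)
  if (nrow(runs) == 0) return(empty)

  # merge runs with a short walking gap between them
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      gap <- traj$t[runs$s[i]] - traj$t[merged$e[nrow(merged)]]
      if (gap < gap_merge) {
        merged$e[nrow(merged)] <- runs$e[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }

  keep <- vector("list", nrow(merged))
  for (i in seq_len(nrow(merged))) {
    idx <- merged$s[i]:merged$e[i]
    o <- ori[idx]
    if (anyNA(o)) {
      warning("candidate scan interval skipped: undefined orientation")
      next
    }
    dur <- traj$t[idx[length(idx)]] - traj$t[idx[1]]
    if (dur < min_dur) next
    cx <- mean(traj$thorax_x[idx]); cy <- mean(traj$thorax_y[idx])
    excur <- max(sqrt((traj$thorax_x[idx] - cx)^2 +
                      (traj$thorax_y[idx] - cy)^2))
    if (excur > r_max) next
    dori <- wrap180(diff(o))
    sweep <- sum(abs(dori))
    if (sweep < theta_min) next
    sgn <- sign(dori[dori != 0])
    reversals <- if (length(sgn) > 1) sum(diff(sgn) != 0) else 0L
    keep[[i]] <- data.frame(
      start_t = traj$t[idx[1]], end_t = traj$t[idx[length(idx)]],
      duration = dur, x = cx, y = cy, total_sweep = sweep,
      n_fixations = reversals + 1L)
  }
  keep <- keep[!vapply(keep, is.null, logical(1))]
  if (length(keep) == 0) return(empty)
  out <- do.call(rbind, keep)
  out <- out[order(out$start_t), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("scan_bouts", "data.frame")
  out
}

#' Summarise detected scanning bouts
#'
#' @param bouts a `scan_bouts` data.frame from [detect_scan_bouts()].
#' @return list with `n_bouts` and `durations` (the full per-bout
#'   duration vector; downstream analyses use per-bout observations).
#' @export
scan_summary <- function(bouts) {
  list(n_bouts = nrow(bouts), durations = bouts$duration)
}
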