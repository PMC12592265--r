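# Synthetic trajectory generator.  Thorax paths are correlated random
# walks: gamma-distributed step lengths (mean p*, CV b*) and
# wrapped-normal turning angles whose concentration is parameterised by
# the population mean cosine c* (sigma = sqrt(-2 log c*)).  The head is
# placed head_offset mm ahead of the thorax along the body axis, which
# oscillates sinusoidally about the direction of travel, as the ants'
# heads do.  Foragers additionally follow a waypoint plan implementing
# one of three responses to the odour band -- cross, detour or U-turn --
# with stop episodes and scanning bouts implanted at scripted times and
# recorded as ground truth.

#' Correlated-random-walk parameters
#'
#' @param mean_step population mean step length p* (mm per frame).
#' @param step_cv population step-length coefficient of variation b*.
#' @param turn_concentration population mean cosine of turning angles
#'   c* in \[0, 1); 0 gives uniform turning.
#' @param drift_direction preferred direction in degrees (90 = up).
#' @param drift_weight weight in \[0, 1) blending the drift direction
#'   into each step's heading (0 = pure CRW).
#' @param frame_rate frames per second.
#' @param head_offset thorax-to-head-tip distance (mm).
#' @param head_osc_amp amplitude of the head's side-to-side sweep about
#'   the direction of travel (deg).
#' @param head_osc_period period of that sweep (s).
#' @return list of class `crw_params`.
#' @export
crw_params <- function(mean_step = 1.5, step_cv = 0.3,
                       turn_concentration = 0.95,
                       drift_direction = 90, drift_weight = 0,
                       frame_rate = 25, head_offset = 3,
                       head_osc_amp = 20, head_osc_period = 1) {
  if (mean_step <= 0) stop_format("mean_step must be > 0")
  if (step_cv < 0) stop_format("step_cv must be >= 0")
  if (turn_concentration < 0 || turn_concentration >= 1)
    stop_format("turn_concentration must lie in [0, 1)")
  if (head_offset <= 0) stop_format("head_offset must be > 0")
  structure(list(mean_step = mean_step, step_cv = step_cv,
                 turn_concentration = turn_concentration,
                 drift_direction = drift_direction,
                 drift_weight = drift_weight,
                 frame_rate = frame_rate, head_offset = head_offset,
                 head_osc_amp = head_osc_amp,
                 head_osc_period = head_osc_period),
            class = "crw_params")
}

# turning angles with population mean cosine cstar
.draw_turns <- function(n, cstar) {
  if (cstar == 0) return(stats::runif(n, -pi, pi))
  sigma <- sqrt(-2 * log(cstar))
  stats::rnorm(n, 0, sigma)
}

# step lengths with mean p and CV b
.draw_steps <- function(n, p, b) {
  if (b == 0) return(rep(p, n))
  stats::rgamma(n, shape = 1 / b^2, scale = p * b^2)
}

# head position and per-frame orientation given thorax path + headings
.add_head <- function(tx, ty, heading_rad, t, params) {
  osc <- deg2rad(params$head_osc_amp) *
    sin(2 * pi * t / params$head_osc_period)
  ori <- heading_rad + osc
  list(hx = tx + params$head_offset * cos(ori),
       hy = ty + params$head_offset * sin(ori),
       ori = ori)
}

#' Simulate a free correlated random walk
#'
#' @param params a [crw_params()] object.
#' @param n_steps number of steps (frames - 1).
#' @param seed integer seed; every output is a pure function of
#'   (params, n_steps, seed).
#' @param start starting thorax position `c(x, y)` (mm).
#' @param ant_id,condition,session trajectory metadata.
#' @return an [trajectory()] object; attribute `ground_truth` records
#'   the population parameters and seed.
#' @export
simulate_crw <- function(params, n_steps, seed, start = c(0, 0),
                         ant_id = "crw", condition = "control",
                         session = "sim") {
  stopifnot(inherits(params, "crw_params"), n_steps >= 2)
  set.seed(seed)
  turns <- .draw_turns(n_steps - 1, params$turn_concentration)
  steps <- .draw_steps(n_steps, params$mean_step, params$step_cv)
  h0 <- deg2rad(params$drift_direction)
  w <- params$drift_weight
  if (w == 0) {
    heading <- h0 + cumsum(c(0, turns))
  } else {
    heading <- numeric(n_steps)
    heading[1] <- h0
    for (i in 2:n_steps) {
      v <- (1 - w) * exp(1i * (heading[i - 1] + turns[i - 1])) +
        w * exp(1i * h0)
      heading[i] <- Arg(v)
    }
  }
  tx <- start[1] + cumsum(c(0, steps * cos(heading)))
  ty <- start[2] + cumsum(c(0, steps * sin(heading)))
  t <- (0:n_steps) / params$frame_rate
  hd <- .add_head(tx, ty, c(heading[1], heading), t, params)
  traj <- trajectory(t, hd$hx, hd$hy, tx, ty, ant_id = ant_id,
                     condition = condition, session = session,
                     frame_rate = params$frame_rate)
  attr(traj, "ground_truth") <- list(
    p_star = params$mean_step, b_star = params$step_cv,
    c_star = params$turn_concentration,
    drift_weight = w, seed = seed, n_steps = n_steps)
  traj
}

#' Behaviour script for a simulated forager
#'
#' @param response_mode `"cross"`, `"detour"` or `"u_turn"`.
#' @param scan_bouts data.frame with columns `start_t` (s), `duration`
#'   (s), `sweep_amp` (deg, half-amplitude of the head sweep); may have
#'   zero rows.
#' @param stop_episodes data.frame with `start_t`, `duration`; the ant
#'   halts without sweeping its head (these must not be detected as
#'   scans).
#' @param sweep_period period of the scanning head sweep (s).
#' @return list of class `behaviour_script`.
#' @export
behaviour_script <- function(response_mode = c("cross", "detour", "u_turn"),
                             scan_bouts = NULL, stop_episodes = NULL,
                             sweep_period = 1) {
  response_mode <- match.arg(response_mode)
  empty <- data.frame(start_t = numeric(0), duration = numeric(0))
  if (is.null(scan_bouts)) {
    scan_bouts <- cbind(empty, sweep_amp = numeric(0))
  }
  if (is.null(stop_episodes)) stop_episodes <- empty
  ev <- rbind(
    if (nrow(scan_bouts))
      data.frame(start_t = scan_bouts$start_t,
                 duration = scan_bouts$duration,
                 sweep_amp = scan_bouts$sweep_amp, kind = "scan"),
    if (nrow(stop_episodes))
      data.frame(start_t = stop_episodes$start_t,
                 duration = stop_episodes$duration,
                 sweep_amp = 0, kind = "stop"))
  if (!is.null(ev) && nrow(ev) > 1) {
    ev <- ev[order(ev$start_t), ]
    if (any(ev$start_t[-1] < (ev$start_t + ev$duration)[-nrow(ev)]))
      stop_format("scripted episodes overlap")
  }
  structure(list(response_mode = response_mode,
                 events = ev %||% cbind(empty, sweep_amp = numeric(0),
                                        kind = character(0)),
                 sweep_period = sweep_period),
            class = "behaviour_script")
}

# Waypoint plan for a response mode.  Each waypoint has a corridor
# half-width; when the ant strays further than that from the current
# leg's straight line, its next heading points straight back at the
# waypoint, which bounds the lateral excursion and makes the three
# geometries unambiguous by construction.
.waypoint_plan <- function(mode, arena, band, x0) {
  w <- arena$width; h <- arena$height
  approach <- c(x0, band$y_min - 40, 30)
  plan <- switch(mode,
    cross = list(approach,
                 c(x0, band$y_max + 40, 30),
                 c(x0, h + 10, 40)),
    detour = {
      room_r <- w - band$x_max
      room_l <- band$x_min
      xd <- if (room_r >= room_l) (band$x_max + w) / 2 else band$x_min / 2
      list(approach,
           c(xd, band$y_min - 30, 20),
           c(xd, band$y_max + 30, 20),
           c(x0, band$y_max + 80, 40),
           c(x0, h + 10, 40))
    },
    u_turn = list(approach,
                  c(x0, -20, 40)))
  plan
}

#' Simulate a forager ascending through the arena
#'
#' An upward-drifting correlated random walk steered along a waypoint
#' plan that realises the script's response to the odour band, with stop
#' episodes and scanning bouts implanted at the scripted times.  The
#' trajectory terminates when the thorax leaves the arena (the frame
#' that exits is kept, mirroring the recording-area windowing).
#'
#' @param params a [crw_params()] object (drift/steering weight taken
#'   from `drift_weight`, floored at 0.35 for waypoint guidance).
#' @param script a [behaviour_script()] object.
#' @param arena an [arena_geometry()] object.
#' @param seed integer seed.
#' @param start starting thorax position; default centred under the band
#'   30 mm up from the arena bottom.
#' @param ant_id,condition,session trajectory metadata.
#' @param max_frames hard cap on trajectory length.
#' @return an [trajectory()] object with attribute `ground_truth`: a
#'   list holding the response mode and a data.frame `events` of the
#'   episodes actually implanted (`kind`, `start_t`, `end_t`,
#'   `duration`).
#' @export
simulate_forager <- function(params, script, arena, seed,
                             start = NULL, ant_id = "forager",
                             condition = "control", session = "sim",
                             max_frames = 30000) {
  stopifnot(inherits(params, "crw_params"),
            inherits(script, "behaviour_script"),
            inherits(arena, "arena_geometry"))
  band <- arena$band
  if (is.null(start))
    start <- c((band$x_min + band$x_max) / 2, 30)
  set.seed(seed)

  plan <- .waypoint_plan(script$response_mode, arena, band, start[1])
  fps <- params$frame_rate
  w_steer <- max(params$drift_weight, 0.35)
  capture <- 10

  turns <- .draw_turns(max_frames, params$turn_concentration)
  steplen <- .draw_steps(max_frames, params$mean_step, params$step_cv)

  ev <- script$events
  ev_next <- if (nrow(ev)) 1L else NA_integer_
  gt_events <- list()

  tx <- numeric(max_frames); ty <- numeric(max_frames)
  ori <- numeric(max_frames)                      # body axis, radians
  tx[1] <- start[1]; ty[1] <- start[2]
  wp_i <- 1L
  leg_from <- start
  h <- atan2(plan[[1]][2] - start[2], plan[[1]][1] - start[1])
  osc <- function(t) deg2rad(params$head_osc_amp) *
    sin(2 * pi * t / params$head_osc_period)
  ori[1] <- h + osc(0)
  i <- 1L

  while (i < max_frames) {
    t_cur <- (i - 1) / fps

    # scripted episode due: freeze the thorax for its duration
    if (!is.na(ev_next) && ev_next <= nrow(ev) &&
        t_cur >= ev$start_t[ev_next]) {
      nf <- max(1L, as.integer(round(ev$duration[ev_next] * fps)))
      nf <- min(nf, max_frames - i)
      amp <- deg2rad(ev$sweep_amp[ev_next])
      ori0 <- ori[i]
      for (j in seq_len(nf)) {
        tx[i + j] <- tx[i]; ty[i + j] <- ty[i]
        ori[i + j] <- ori0 +
          amp * sin(2 * pi * (j / fps) / script$sweep_period)
      }
      gt_events[[length(gt_events) + 1]] <- data.frame(
        kind = ev$kind[ev_next],
        start_t = t_cur, end_t = t_cur + nf / fps,
        duration = nf / fps)
      i <- i + nf
      ev_next <- ev_next + 1L
      next
    }

    wp <- plan[[wp_i]]
    dx <- wp[1] - tx[i]; dy <- wp[2] - ty[i]
    if (sqrt(dx^2 + dy^2) < capture) {
      if (wp_i == length(plan)) break
      leg_from <- c(tx[i], ty[i])
      wp_i <- wp_i + 1L
      wp <- plan[[wp_i]]
      dx <- wp[1] - tx[i]; dy <- wp[2] - ty[i]
    }
    desired <- atan2(dy, dx)
    # perpendicular distance from the current leg's line
    lx <- wp[1] - leg_from[1]; ly <- wp[2] - leg_from[2]
    ll <- sqrt(lx^2 + ly^2)
    lat <- abs(lx * (ty[i] - leg_from[2]) - ly * (tx[i] - leg_from[1])) / ll
    if (lat > wp[3]) {
      h <- desired
    } else {
      v <- (1 - w_steer) * exp(1i * (h + turns[i])) +
        w_steer * exp(1i * desired)
      h <- Arg(v)
    }
    tx[i + 1] <- tx[i] + steplen[i] * cos(h)
    ty[i + 1] <- ty[i] + steplen[i] * sin(h)
    ori[i + 1] <- h + osc(i / fps)
    i <- i + 1L
    if (tx[i] < 0 || tx[i] > arena$width || ty[i] < 0 || ty[i] > arena$height)
      break
  }

  n <- i
  t <- (0:(n - 1)) / fps
  tx <- tx[1:n]; ty <- ty[1:n]; ori <- ori[1:n]
  traj <- trajectory(t,
                     tx + params$head_offset * cos(ori),
                     ty + params$head_offset * sin(ori),
                     tx, ty, ant_id = ant_id, condition = condition,
                     session = session, frame_rate = fps)
  attr(traj, "ground_truth") <- list(
    response_mode = script$response_mode,
    events = if (length(gt_events)) do.call(rbind, gt_events) else
      data.frame(kind = character(0), start_t = numeric(0),
                 end_t = numeric(0), duration = numeric(0)),
    params = params, seed = seed)
  traj
}

#' Condition profiles emulating an acute odour response
#'
#' Control ants ascend nearly straight, fast, with a single scanning
#' bout; test ants turn more (lower c*), step more slowly, scan more,
#' and mostly detour or U-turn at the band.
#'
#' @return named list of per-condition profiles consumed by
#'   [simulate_experiment()].
#' @export
odour_effect_profiles <- function() {
  list(
    control = list(turn_concentration = 0.95, mean_step = 1.5,
                   n_scans = 1, scan_duration = 1.0, scan_amp = 60,
                   mode_probs = c(cross = 1, detour = 0, u_turn = 0)),
    test = list(turn_concentration = 0.75, mean_step = 1.0,
                n_scans = 4, scan_duration = 1.5, scan_amp = 60,
                mode_probs = c(cross = 0.2, detour = 0.7, u_turn = 0.1)))
}

#' Condition profiles emulating habituation over repeated exposure
#'
#' Day 1 shows the full aversive shift, day 2 a partial recovery, day 3
#' is close to control.
#'
#' @return named list of per-condition profiles (control, day1, day2,
#'   day3) for [simulate_experiment()].
#' @export
habituation_profiles <- function() {
  list(
    control = list(turn_concentration = 0.95, mean_step = 1.5,
                   n_scans = 1, scan_duration = 1.0, scan_amp = 60,
                   mode_probs = c(cross = 1, detour = 0, u_turn = 0)),
    day1 = list(turn_concentration = 0.75, mean_step = 1.0,
                n_scans = 4, scan_duration = 1.5, scan_amp = 60,
                mode_probs = c(cross = 0.1, detour = 0.8, u_turn = 0.1)),
    day2 = list(turn_concentration = 0.87, mean_step = 1.25,
                n_scans = 2, scan_duration = 1.2, scan_amp = 60,
                mode_probs = c(cross = 0.4, detour = 0.55, u_turn = 0.05)),
    day3 = list(turn_concentration = 0.93, mean_step = 1.45,
                n_scans = 1, scan_duration = 1.0, scan_amp = 60,
                mode_probs = c(cross = 0.85, detour = 0.15, u_turn = 0)))
}

# scripted scan times spread through the expected ascent; the count is
# Poisson around the profile mean, as per-ant scan counts vary widely
.scan_times <- function(mean_scans, profile, arena, fps) {
  n_scans <- stats::rpois(1, mean_scans)
  if (n_scans < 1) return(numeric(0))
  est <- (arena$height - 30) / (profile$mean_step * fps)
  lo <- 2; hi <- max(lo + 1, 0.7 * est)
  base <- seq(lo, hi, length.out = n_scans + 1)[-1]
  base + stats::runif(n_scans, -0.3, 0.3)
}

#' Simulate a full experiment with known ground truth
#'
#' Two designs: `"between"` generates independent ants per condition
#' (the acute-response layout); `"within"` reuses the same subjects
#' across all conditions (the habituation layout) with per-subject
#' random intercepts on step length (hence speed) and on the turning
#' concentration c*.
#'
#' @param profiles named list of per-condition profiles, e.g.
#'   [odour_effect_profiles()]; each profile may set any [crw_params()]
#'   field plus `n_scans` (mean implanted scanning bouts per trip; the
#'   per-ant count is Poisson), `scan_duration`, `scan_amp`,
#'   `mode_probs`.
#' @param n_per_cell ants (or subjects) per condition (>= 2).
#' @param seed integer seed.
#' @param design `"between"` or `"within"`.
#' @param arena an [arena_geometry()] object.
#' @param dir if non-NULL, trajectories are written there as CSV and the
#'   manifest records the file paths.
#' @param subject_sd_step,subject_sd_c within-design random-intercept
#'   SDs (log step multiplier; additive c* shift).
#' @return list with `trajectories` (list of [trajectory()] objects),
#'   `manifest` (data.frame: ant_id, condition, session, subject, file)
#'   and `truth` (data.frame: per-ant response mode and implanted scan
#'   count).
#' @export
simulate_experiment <- function(profiles, n_per_cell, seed,
                                design = c("between", "within"),
                                arena = arena_geometry(), dir = NULL,
                                subject_sd_step = 0.08,
                                subject_sd_c = 0.015) {
  design <- match.arg(design)
  if (n_per_cell < 2) stop_format("n_per_cell must be >= 2")
  set.seed(seed)
  conditions <- names(profiles)
  seeds <- sample.int(.Machine$integer.max - 1,
                      n_per_cell * length(conditions))
  if (design == "within") {
    subj_step <- exp(stats::rnorm(n_per_cell, 0, subject_sd_step))
    subj_c <- stats::rnorm(n_per_cell, 0, subject_sd_c)
  }
  event_seeds <- sample.int(.Machine$integer.max - 1,
                            n_per_cell * length(conditions))

  trajs <- list(); manifest <- list(); truth <- list()
  idx <- 0
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    prof <- profiles[[cond]]
    for (a in seq_len(n_per_cell)) {
      idx <- idx + 1
      pars <- list(mean_step = prof$mean_step %||% 1.5,
                   step_cv = prof$step_cv %||% 0.3,
                   turn_concentration = prof$turn_concentration %||% 0.95,
                   frame_rate = prof$frame_rate %||% 25)
      if (design == "within") {
        pars$mean_step <- pars$mean_step * subj_step[a]
        pars$turn_concentration <-
          min(0.99, max(0, pars$turn_concentration + subj_c[a]))
      }
      params <- do.call(crw_params, pars)
      set.seed(event_seeds[idx])
      mp <- prof$mode_probs %||% c(cross = 1, detour = 0, u_turn = 0)
      mode <- sample(names(mp), 1, prob = mp)
      st <- .scan_times(prof$n_scans %||% 0, prof, arena,
                        params$frame_rate)
      scans <- if (length(st)) {
        data.frame(start_t = st,
                   duration = prof$scan_duration %||% 1.0,
                   sweep_amp = prof$scan_amp %||% 60)
      } else NULL
      script <- behaviour_script(mode, scan_bouts = scans)
      ant_id <- sprintf("%s_%02d", cond, a)
      label <- if (cond == "control") "control" else "test"
      traj <- simulate_forager(params, script, arena, seeds[idx],
                               ant_id = ant_id, condition = label,
                               session = cond)
      gt <- attr(traj, "ground_truth")
      file <- NA_character_
      if (!is.null(dir)) {
        file <- file.path(dir, paste0(ant_id, ".csv"))
        write_trajectory(traj, file)
      }
      trajs[[idx]] <- traj
      manifest[[idx]] <- data.frame(
        ant_id = ant_id, condition = label, session = cond,
        subject = a, file = file, stringsAsFactors = FALSE)
      truth[[idx]] <- data.frame(
        ant_id = ant_id, session = cond, subject = a,
        response_mode = mode,
        n_scans_implanted = sum(gt$events$kind == "scan"),
        stringsAsFactors = FALSE)
    }
  }
  out <- list(trajectories = trajs,
              manifest = do.call(rbind, manifest),
              truth = do.call(rbind, truth))
  if (!is.null(dir)) {
    write_metrics_table(out$manifest, file.path(dir, "manifest.csv"))
    write_metrics_table(out$truth, file.path(dir, "truth.csv"))
  }
  out
}

#' Per-ant summary across kinematics, straightness and scanning
#'
#' @param traj an [trajectory()] object.
#' @param arena an [arena_geometry()] object or NULL.
#' @param v_stop stop threshold (mm/s).
#' @param ... scan-detector thresholds passed to [detect_scan_bouts()].
#' @return one-row data.frame: [path_metrics()] columns plus `n_scans`,
#'   `total_scan_time`, `mean_scan_duration`.
#' @export
summarise_trajectory <- function(traj, arena = NULL, v_stop = 0.01, ...) {
  pm <- path_metrics(traj, arena = arena, v_stop = v_stop)
  bouts <- detect_scan_bouts(traj, v_stop = v_stop, ...)
  sc <- scan_summary(bouts)
  pm$n_scans <- sc$n_bouts
  pm$total_scan_time <- sum(sc$durations)
  pm$mean_scan_duration <- if (sc$n_bouts) mean(sc$durations) else 0
  pm
}

#' @rdname summarise_trajectory
#' @param trajs list of trajectories.
#' @export
summarise_trajectories <- function(trajs, arena = NULL, v_stop = 0.01, ...) {
  out <- do.call(rbind, lapply(trajs, summarise_trajectory,
                               arena = arena, v_stop = v_stop, ...))
  rownames(out) <- NULL
  out
}
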