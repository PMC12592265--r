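# Independent brute-force oracles and fixture builders.  These stay
# deliberately naive -- loops and first-principles formulas -- so they
# cannot share a defect with the implementation they check.

# trajectory from a thorax point matrix; head placed 3 mm to the +x of
# the thorax unless a heading vector is supplied
traj_from_thorax <- function(xy, fps = 25, head_angle = 0, ...) {
  n <- nrow(xy)
  ha <- rep(head_angle, length.out = n) * pi / 180
  trajectory(t = (0:(n - 1)) / fps,
             head_x = xy[, 1] + 3 * cos(ha),
             head_y = xy[, 2] + 3 * sin(ha),
             thorax_x = xy[, 1], thorax_y = xy[, 2],
             frame_rate = fps, ...)
}

# straight upward walk at constant speed (mm/s), optionally with an
# implanted full stop of stop_dur seconds after stop_after seconds
straight_walk <- function(speed = 10, n = 100, fps = 25,
                          stop_after = NULL, stop_dur = 0) {
  step <- speed / fps
  y <- cumsum(rep(step, n - 1))
  y <- c(0, y)
  if (!is.null(stop_after)) {
    i <- round(stop_after * fps) + 1
    nf <- round(stop_dur * fps)
    y <- c(y[1:i], rep(y[i], nf), y[(i + 1):n] )
  }
  traj_from_thorax(cbind(0, y), fps = fps, head_angle = 90)
}

oracle_pair_dist <- function(xy) {
  n <- nrow(xy)
  d <- numeric(n - 1)
  for (i in 1:(n - 1)) {
    d[i] <- sqrt((xy[i + 1, 1] - xy[i, 1])^2 + (xy[i + 1, 2] - xy[i, 2])^2)
  }
  d
}

# wrapped heading difference through unit phasors
oracle_turn_phasor <- function(h1, h2) {
  Arg(exp(1i * h2 * pi / 180) / exp(1i * h1 * pi / 180)) * 180 / pi
}

# stop-excluded mean speed: mask sub-threshold steps, then divide sums
oracle_masked_speed <- function(traj, v_stop) {
  dt <- diff(traj$t)
  dx <- diff(traj$thorax_x); dy <- diff(traj$thorax_y)
  len <- sqrt(dx^2 + dy^2)
  keep <- len / dt >= v_stop
  list(mean_speed = sum(len[keep]) / sum(dt[keep]),
       stopped_time = sum(dt[!keep]))
}

# single-pass sinuosity from raw step lengths and turning angles
oracle_sinuosity <- function(steps, turns) {
  steps <- steps[!is.na(steps)]; turns <- turns[!is.na(turns)]
  p <- sum(steps) / length(steps)
  cc <- sum(cos(turns * pi / 180)) / length(turns)
  b <- sqrt(sum((steps - p)^2) / length(steps)) / p
  2 * (p * ((1 + cc) / (1 - cc) + b^2))^(-0.5)
}

oracle_emax <- function(turns) {
  turns <- turns[!is.na(turns)]
  beta <- sum(cos(turns * pi / 180)) / length(turns)
  beta / (1 - beta)
}

# textbook Welch t with Satterthwaite df
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# within-subject ANOVA by explicit sums of squares
oracle_rm_anova <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  F <- (ss_cond / df1) / (ss_err / df2)
  list(F = F, df_num = df1, df_den = df2,
       p = pf(F, df1, df2, lower.tail = FALSE))
}

# CRW ground-truth sinuosity from population parameters
population_sinuosity <- function(p, c, b) {
  2 * (p * ((1 + c) / (1 - c) + b^2))^(-0.5)
}

default_arena <- function() arena_geometry()

# hand-built route exemplars against the default 700 x 1000 arena
# (band x 100..600, y 475..525)
exemplar_cross <- function() {
  y <- seq(20, 980, by = 4)
  traj_from_thorax(cbind(350, y), head_angle = 90)
}
exemplar_detour <- function() {
  pts <- rbind(cbind(350, seq(20, 420, by = 4)),
               cbind(seq(354, 650, by = 4), 420),
               cbind(650, seq(424, 580, by = 4)),
               cbind(seq(646, 350, by = -4), 580),
               cbind(350, seq(584, 980, by = 4)))
  traj_from_thorax(pts, head_angle = 90)
}
exemplar_uturn <- function() {
  pts <- rbind(cbind(350, seq(20, 455, by = 4)),
               cbind(350, seq(451, 1, by = -4)))
  traj_from_thorax(pts, head_angle = 90)
}

mirror_x <- function(traj, about) {
  out <- trajectory(traj$t,
                    2 * about - traj$head_x, traj$head_y,
                    2 * about - traj$thorax_x, traj$thorax_y,
                    ant_id = attr(traj, "ant_id"),
                    condition = attr(traj, "condition"),
                    session = attr(traj, "session"),
                    frame_rate = attr(traj, "frame_rate"))
  out
}
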