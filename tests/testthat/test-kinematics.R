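test_that("steps are Euclidean thorax displacements with atan2 headings", {
  tr <- traj_from_thorax(rbind(c(0, 0), c(3, 4)))
  st <- compute_steps(tr)
  expect_equal(st$length, 5)
  expect_equal(st$heading, atan2(4, 3) * 180 / pi)

  tr2 <- traj_from_thorax(rbind(c(1, 1), c(1, 1)))
  st2 <- compute_steps(tr2)
  expect_equal(st2$length, 0)
  expect_true(is.na(st2$heading))

  expect_error(compute_steps(traj_from_thorax(cbind(0, 0))),
               class = "antnav_insufficient_data")
})

test_that("step lengths match the brute-force pairwise oracle", {
  set.seed(101)
  xy <- cbind(cumsum(rnorm(100)), cumsum(rnorm(100)))
  st <- compute_steps(traj_from_thorax(xy))
  expect_lt(max(abs(st$length - oracle_pair_dist(xy))), 1e-12)
})

test_that("turning angles wrap to (-180, 180] and skip undefined headings", {
  # collinear equally spaced points turn by zero
  tr <- traj_from_thorax(cbind(1:10, 2 * (1:10)))
  expect_equal(as.numeric(compute_turning_angles(compute_steps(tr)$heading)),
               rep(0, 8))

  # left-turning staircase: all +90
  xy <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0), c(1, 0))
  turns <- compute_turning_angles(compute_steps(traj_from_thorax(xy))$heading)
  expect_equal(as.numeric(turns), rep(90, 4))

  # wrap-around: 170 deg then -170 deg is a +20 turn
  expect_equal(as.numeric(compute_turning_angles(c(170, -170))), 20)
  expect_equal(oracle_turn_phasor(170, -170), 20)

  # zero-length step: the two adjacent pairs are skipped and counted
  xy2 <- rbind(c(0, 0), c(1, 0), c(1, 0), c(2, 0), c(3, 0))
  t2 <- compute_turning_angles(compute_steps(traj_from_thorax(xy2))$heading)
  expect_equal(attr(t2, "n_skipped"), 2)
  expect_equal(sum(is.na(t2)), 2)
})

test_that("turning angles agree with the complex-phasor oracle everywhere", {
  set.seed(7)
  h <- runif(500, -720, 720)
  turns <- as.numeric(compute_turning_angles(h))
  for (i in seq_along(turns)) {
    expect_lt(abs(turns[i] - oracle_turn_phasor(h[i], h[i + 1])), 1e-9)
  }
  expect_true(all(turns > -180 & turns <= 180))
})

test_that("stop-excluded speed follows the mask-and-divide rule", {
  tr <- straight_walk(speed = 10, n = 100)
  sp <- compute_speed_series(tr)
  expect_equal(sp$summary$mean_speed, 10)
  expect_equal(sp$summary$stopped_time, 0)

  # 10 s moving at 10 mm/s plus a 5 s full stop: mean stays 10
  tr2 <- straight_walk(speed = 10, n = 251, stop_after = 5, stop_dur = 5)
  sp2 <- compute_speed_series(tr2)
  expect_equal(sp2$summary$mean_speed, 10)
  expect_equal(sp2$summary$stopped_time, 5)
  expect_equal(sp2$summary$total_moving_distance, 100)

  # identity: mean_speed * moving time = moving distance
  expect_equal(sp2$summary$mean_speed * sp2$summary$total_moving_time,
               sp2$summary$total_moving_distance)
  expect_equal(sp2$summary$stopped_time + sp2$summary$total_moving_time,
               sp2$summary$total_duration)
})

test_that("random walks with implanted stops match the masking oracle", {
  set.seed(11)
  for (rep in 1:5) {
    xy <- cbind(cumsum(rnorm(200, sd = 0.5)), cumsum(rnorm(200, sd = 0.5)))
    idx <- sort(sample(50:150, 2))
    xy[idx[1]:idx[2], ] <- rep(xy[idx[1], ], each = idx[2] - idx[1] + 1)
    tr <- traj_from_thorax(xy)
    sp <- compute_speed_series(tr, v_stop = 0.01)
    orc <- oracle_masked_speed(tr, 0.01)
    expect_equal(sp$summary$mean_speed, orc$mean_speed, tolerance = 1e-12)
    expect_equal(sp$summary$stopped_time, orc$stopped_time)
  }
})

test_that("a fully stopped trajectory is flagged, not zeroed", {
  tr <- traj_from_thorax(cbind(rep(1, 10), rep(2, 10)))
  sp <- compute_speed_series(tr)
  expect_true(is.na(sp$summary$mean_speed))
  expect_true(sp$summary$all_stopped)
})

test_that("orientation is the thorax-through-head direction", {
  tr <- trajectory(t = c(0, 0.04), head_x = c(0, 0), head_y = c(3, 3),
                   thorax_x = c(0, 0), thorax_y = c(0, 0))
  expect_equal(as.numeric(compute_orientation_series(tr)), c(90, 90))

  # coincident points: undefined and counted
  tr2 <- trajectory(t = c(0, 0.04), head_x = c(0, 1), head_y = c(3, 0),
                    thorax_x = c(0, 1), thorax_y = c(0, 0))
  ori <- compute_orientation_series(tr2)
  expect_true(is.na(ori[2]))
  expect_equal(attr(ori, "n_undefined"), 1)

  set.seed(5)
  hx <- rnorm(50); hy <- rnorm(50); tx <- rnorm(50); ty <- rnorm(50)
  tr3 <- trajectory((0:49) / 25, hx, hy, tx, ty)
  expect_equal(as.numeric(compute_orientation_series(tr3)),
               atan2(hy - ty, hx - tx) * 180 / pi)
})

test_that("uniform rotation at 90 deg/s gives mean |omega| of exactly 90", {
  t <- (0:250) / 25
  ang <- 90 * t                       # sweeps several full turns
  tr <- trajectory(t, head_x = 3 * cos(ang * pi / 180),
                   head_y = 3 * sin(ang * pi / 180),
                   thorax_x = 0 * t, thorax_y = 0 * t)
  av <- compute_angular_velocity(compute_orientation_series(tr), t)
  expect_equal(av$mean_abs, 90)
  expect_equal(av$mean_signed, 90)

  # constant orientation
  av0 <- compute_angular_velocity(rep(45, 10), (0:9) / 25)
  expect_equal(av0$mean_abs, 0)
})

test_that("oscillating sweeps across the +-180 cut match the unwrap oracle", {
  t <- (0:200) / 25
  ang <- 170 + 60 * sin(2 * pi * t)   # repeatedly crosses the angle cut
  tr <- trajectory(t, head_x = 3 * cos(ang * pi / 180),
                   head_y = 3 * sin(ang * pi / 180),
                   thorax_x = 0 * t, thorax_y = 0 * t)
  ori <- compute_orientation_series(tr)
  av <- compute_angular_velocity(ori, t)
  # oracle: unwrap the atan2 series cumulatively, then difference
  d <- diff(as.numeric(ori))
  d <- d - 360 * round(d / 360)
  unwrapped <- cumsum(c(as.numeric(ori)[1], d))
  omega_oracle <- diff(unwrapped) / diff(t)
  expect_lt(max(abs(av$omega - omega_oracle)), 1e-9)
  expect_equal(av$mean_abs, mean(abs(omega_oracle)))
})

test_that("rigid rotation leaves invariant quantities invariant", {
  set.seed(13)
  xy <- cbind(cumsum(rnorm(80)), cumsum(rnorm(80)))
  tr <- traj_from_thorax(xy, head_angle = runif(80, -180, 180))
  phi <- 37.5 * pi / 180
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
  rot <- function(x, y) cbind(x, y) %*% t(R)
  h <- rot(tr$head_x, tr$head_y); th <- rot(tr$thorax_x, tr$thorax_y)
  tr_rot <- trajectory(tr$t, h[, 1], h[, 2], th[, 1], th[, 2])

  k1 <- trajectory_kinematics(tr); k2 <- trajectory_kinematics(tr_rot)
  expect_lt(max(abs(k1$steps$length - k2$steps$length)), 1e-9)
  expect_lt(max(abs(as.numeric(k1$turning_angles) -
                    as.numeric(k2$turning_angles))), 1e-9)
  expect_lt(max(abs(k1$speed - k2$speed)), 1e-9)
  expect_lt(abs(k1$angular_velocity$mean_abs -
                k2$angular_velocity$mean_abs), 1e-9)
  dh <- wrap180(k2$steps$heading - k1$steps$heading - 37.5)
  expect_lt(max(abs(dh)), 1e-9)
})

test_that("uniform time rescaling divides speeds and omega exactly", {
  set.seed(17)
  xy <- cbind(cumsum(rnorm(60)), cumsum(rnorm(60)))
  tr <- traj_from_thorax(xy, head_angle = seq(0, 300, length.out = 60))
  k <- 3
  tr_slow <- trajectory(tr$t * k, tr$head_x, tr$head_y,
                        tr$thorax_x, tr$thorax_y)
  s1 <- compute_speed_series(tr, v_stop = 0)
  s2 <- compute_speed_series(tr_slow, v_stop = 0)
  expect_equal(s2$speed, s1$speed / k)
  o1 <- compute_angular_velocity(compute_orientation_series(tr), tr$t)
  o2 <- compute_angular_velocity(compute_orientation_series(tr_slow),
                                 tr_slow$t)
  expect_equal(o2$omega, o1$omega / k)
  expect_equal(o2$mean_abs, o1$mean_abs / k)
})
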