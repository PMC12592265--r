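test_that("generation is a pure function of parameters and seed", {
  p <- crw_params(turn_concentration = 0.8)
  a <- simulate_crw(p, 500, seed = 5)
  b <- simulate_crw(p, 500, seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_crw(p, 500, seed = 6)
  expect_false(identical(a$thorax_x, c$thorax_x))

  arena <- default_arena()
  scr <- behaviour_script("detour",
                          scan_bouts = data.frame(start_t = 5,
                                                  duration = 1,
                                                  sweep_amp = 60))
  f1 <- simulate_forager(crw_params(), scr, arena, seed = 8)
  f2 <- simulate_forager(crw_params(), scr, arena, seed = 8)
  expect_identical(as.data.frame(f1), as.data.frame(f2))

  s1 <- simulate_experiment(odour_effect_profiles(), 4, seed = 3)
  s2 <- simulate_experiment(odour_effect_profiles(), 4, seed = 3)
  expect_identical(s1$manifest, s2$manifest)
  expect_identical(s1$truth, s2$truth)
  expect_identical(as.data.frame(s1$trajectories[[5]]),
                   as.data.frame(s2$trajectories[[5]]))
})

test_that("parameter validation rejects impossible settings", {
  expect_error(crw_params(turn_concentration = 1), "turn_concentration")
  expect_error(crw_params(mean_step = -1), "mean_step")
  expect_error(behaviour_script("sideways"))
  expect_error(
    behaviour_script("cross",
                     scan_bouts = data.frame(start_t = c(2, 2.5),
                                             duration = c(1, 1),
                                             sweep_amp = 60)),
    "overlap")
  expect_error(simulate_experiment(odour_effect_profiles(), 1, seed = 1),
               "n_per_cell")
})

test_that("uniform turning gives a mean cosine near zero", {
  n <- 10000
  tr <- simulate_crw(crw_params(turn_concentration = 0), n, seed = 17)
  k <- trajectory_kinematics(tr)
  beta <- mean(cos(as.numeric(k$turning_angles) * pi / 180), na.rm = TRUE)
  expect_lt(abs(beta), 3 / sqrt(n))
})

test_that("sample p, b and c recover the population values within 3 SE", {
  p_star <- 1.5; b_star <- 0.3; c_star <- 0.9
  n <- 10000
  tr <- simulate_crw(crw_params(mean_step = p_star, step_cv = b_star,
                                turn_concentration = c_star), n, seed = 29)
  k <- trajectory_kinematics(tr)
  steps <- k$steps$length
  turns <- as.numeric(k$turning_angles)

  se_p <- sd(steps) / sqrt(length(steps))
  expect_lt(abs(mean(steps) - p_star), 3 * se_p)

  cs <- cos(turns * pi / 180)
  se_c <- sd(cs) / sqrt(length(cs))
  expect_lt(abs(mean(cs) - c_star), 3 * se_c)

  # delta-method standard error for the CV
  m <- mean(steps); v <- mean((steps - m)^2)
  mu3 <- mean((steps - m)^3); mu4 <- mean((steps - m)^4)
  db_dm <- -sqrt(v) / m^2; db_dv <- 1 / (2 * m * sqrt(v))
  var_b <- (db_dm^2 * v + db_dv^2 * (mu4 - v^2) +
            2 * db_dm * db_dv * mu3) / length(steps)
  b_hat <- sqrt(v) / m
  expect_lt(abs(b_hat - b_star), 3 * sqrt(var_b))
})

test_that("simulated foragers execute their scripted response modes", {
  arena <- default_arena()
  for (mode in c("cross", "detour", "u_turn")) {
    tr <- simulate_forager(crw_params(), behaviour_script(mode),
                           arena, seed = 61)
    expected <- c(cross = "walked_over", detour = "detour",
                  u_turn = "u_turn")[[mode]]
    expect_equal(classify_route(tr, arena)$category, expected)
  }
  # U-turners end back below their start height
  tu <- simulate_forager(crw_params(), behaviour_script("u_turn"),
                         arena, seed = 62)
  expect_lt(tu$thorax_y[nrow(tu)], arena$band$y_min)
  expect_lte(tu$thorax_y[nrow(tu)], tu$thorax_y[1])
})

test_that("scripted scan bouts are found exactly by the detector", {
  arena <- default_arena()
  scr <- behaviour_script("cross",
                          scan_bouts = data.frame(start_t = c(4, 10, 16),
                                                  duration = 1.2,
                                                  sweep_amp = 60))
  tr <- simulate_forager(crw_params(), scr, arena, seed = 71)
  gt <- attr(tr, "ground_truth")$events
  expect_equal(nrow(gt), 3)
  bouts <- detect_scan_bouts(tr)
  expect_equal(nrow(bouts), 3)
  expect_true(all(abs(bouts$start_t - gt$start_t) <= 1 / 25 + 1e-9))
  expect_true(all(abs(bouts$end_t - gt$end_t) <= 1 / 25 + 1e-9))
})

test_that("within-subject designs reuse subjects with random intercepts", {
  sim <- simulate_experiment(habituation_profiles(), n_per_cell = 6,
                             seed = 81, design = "within")
  expect_equal(nrow(sim$manifest), 24)
  expect_equal(sort(unique(sim$manifest$subject)), 1:6)
  expect_setequal(unique(sim$manifest$session),
                  c("control", "day1", "day2", "day3"))
  # every subject appears once per condition
  expect_true(all(table(sim$manifest$subject, sim$manifest$session) == 1))
})
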