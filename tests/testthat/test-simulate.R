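test_that("path simulation is seed-deterministic and geometry-respecting", {
  agent <- agent_params(dispersion = 15, speed = 140)
  p1 <- simulate_path(agent, default_geom, seed = 9)
  p2 <- simulate_path(agent, default_geom, seed = 9)
  expect_identical(p1, p2)
  p3 <- simulate_path(agent, default_geom, seed = 10)
  expect_false(identical(p1$x_mm, p3$x_mm))

  # endpoints at the circle centers by construction
  expect_equal(c(p1$x_mm[1], p1$y_mm[1]), default_geom$start_center)
  expect_equal(c(tail(p1$x_mm, 1), tail(p1$y_mm, 1)),
               default_geom$end_center)
})

test_that("a dispersionless agent draws the straight chord", {
  agent <- agent_params(dispersion = 0, speed = 140)
  p <- simulate_path(agent, default_geom, seed = 1)
  expect_lt(max(abs(p$x_mm - 254.5)), 1e-9)
  # two such paths are exact duplicates in shape: uniqueness 0
  tr <- dplyr::bind_rows(
    make_traj(p$x_mm, p$y_mm, t = p$t_s, path_id = "p001"),
    make_traj(p$x_mm, p$y_mm, t = p$t_s, path_id = "p002")
  )
  u <- uniqueness_scores(path_features(resample_paths(tr), default_geom))
  expect_equal(u$ui, c(0, 0))
})

test_that("sessions respect the time budget and produce only valid paths", {
  agent <- agent_params(dispersion = 18, speed = 120)
  sess <- simulate_session(agent, default_geom, seed = 2)
  truth <- attr(sess, "truth")
  expect_gt(nrow(truth), 3)
  # activity (durations plus inter-path gaps) fits in the budget
  expect_lte(max(truth$onset + truth$duration), default_geom$time_limit)
  expect_true(all(truth$onset >= 0 &
                    truth$onset <= default_geom$time_limit))
  flags <- validate_paths(sess, default_geom)
  expect_true(all(flags$valid))
  # per-path drawing duration equals the generative duration
  expect_equal(flags$duration_s[order(flags$path_id)],
               truth$duration[order(truth$path_id)], tolerance = 1e-6)
})

test_that("doubling speed raises fluency; dispersion costs time", {
  slow <- agent_params(dispersion = 15, speed = 90, uniqueness_cost = 0.35)
  fast <- agent_params(dispersion = 15, speed = 180, uniqueness_cost = 0.35)
  n_slow <- nrow(attr(simulate_session(slow, default_geom, seed = 3), "truth"))
  n_fast <- nrow(attr(simulate_session(fast, default_geom, seed = 3), "truth"))
  expect_gt(n_fast, n_slow)

  tight <- agent_params(dispersion = 30, speed = 90, uniqueness_cost = 0.35)
  n_tight <- nrow(attr(simulate_session(tight, default_geom, seed = 3), "truth"))
  expect_gt(n_slow, n_tight)
})

test_that("cohort simulation is reproducible and counterbalances conditions", {
  cfg <- generator_config(n_agents = 4, seed = 51)
  ch1 <- simulate_cohort(cfg, design = "ON_OFF_crossover")
  ch2 <- simulate_cohort(cfg, design = "ON_OFF_crossover")
  expect_identical(ch1$trajectories, ch2$trajectories)
  expect_identical(ch1$covariates, ch2$covariates)

  first_cond <- ch1$trajectories |>
    dplyr::filter(session_index == 1) |>
    dplyr::distinct(participant_id, condition)
  expect_setequal(unique(first_cond$condition), c("ON", "OFF"))
  # every agent sees both conditions
  conds <- ch1$trajectories |>
    dplyr::distinct(participant_id, condition) |>
    dplyr::count(participant_id)
  expect_true(all(conds$n == 2))
})

test_that("a null condition design centres paired differences on zero", {
  cfg <- generator_config(n_agents = 10, seed = 52,
                          condition_effects = list())
  ch <- simulate_cohort(cfg, design = "drug_placebo_crossover")
  s <- summarize_sessions(ch, score_paths(ch))
  wide <- tidyr::pivot_wider(
    dplyr::select(s, participant_id, condition, fluency),
    names_from = condition, values_from = fluency
  )
  d <- wide$drug - wide$placebo
  # mean |difference| stays within sampling noise of zero
  expect_lt(abs(mean(d)) / (sd(d) / sqrt(length(d)) + 1e-9), 3)
})

test_that("control tasks reproduce their stated designs", {
  agent <- agent_params(dispersion = 12, speed = 140)

  motor <- simulate_control_task(agent, default_geom, "motor_execution",
                                 seed = 6)
  expect_equal(dplyr::n_distinct(motor$path_id), 10)
  expect_true(all(validate_paths(motor, default_geom)$valid))

  cued <- simulate_control_task(agent, default_geom, "cued_action",
                                seed = 7)
  tg <- attr(cued, "targets")
  expect_true(all(tg$angle_deg >= -90 & tg$angle_deg <= 90))
  # all targets at the task distance from the start circle
  d_t <- sqrt((tg$target_x - 254.5)^2 + (tg$target_y - 41)^2)
  expect_equal(d_t, rep(204, nrow(tg)), tolerance = 1e-9)
  # 90 s budget respected
  expect_lte(max(cued$t_s), 90)

  sel <- simulate_control_task(agent, default_geom, "option_selection",
                               seed = 8)
  slots <- seq(-90, 90, length.out = 24)
  expect_true(all(attr(sel, "targets")$angle_deg %in% slots))
  expect_lte(max(sel$t_s), 90)
  # start-side validity still enforced for target tasks
  expect_true(all(validate_paths(sel, default_geom)$valid))
})

test_that("generator invariants: population draws respect their links", {
  cfg <- generator_config(n_agents = 40, seed = 53)
  ch <- simulate_cohort(cfg)
  agents <- attr(ch, "agents")
  expect_equal(nrow(agents), 40)
  # motivated agents are less disperse by construction
  expect_lt(cor(agents$motivation, log(agents$dispersion)), -0.3)
  expect_true(all(agents$speed > 0))
  # covariates carry the same values
  s <- summarize_sessions(ch, score_paths(ch))
  expect_equal(
    s$motivation[match(agents$participant_id, s$participant_id)],
    agents$motivation
  )
})
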