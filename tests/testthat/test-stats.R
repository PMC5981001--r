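test_that("session summaries aggregate fluency, uniqueness and covariates", {
  ch <- simulate_cohort(generator_config(n_agents = 3, seed = 31))
  m <- score_paths(ch)
  s <- summarize_sessions(ch, m)
  expect_equal(nrow(s), 3)
  # brute-force recount per session
  for (i in seq_len(nrow(s))) {
    rows <- m[m$participant_id == s$participant_id[i] &
                m$session_index == s$session_index[i], ]
    expect_equal(s$fluency[i], sum(rows$valid))
    expect_equal(s$mean_uniqueness[i], mean(rows$ui[rows$valid]))
  }
  expect_true(all(c("motivation", "apathy") %in% names(s)))
})

test_that("hand-built metrics summarize to the expected means and flag empty sessions", {
  tr <- dplyr::bind_rows(
    straight_traj(path_id = "p1"),
    random_session(n_paths = 2, sigma = 10, seed = 1) |>
      dplyr::filter(path_id == "p001") |>
      dplyr::mutate(path_id = "p2"),
    random_session(n_paths = 2, sigma = 30, seed = 2) |>
      dplyr::filter(path_id == "p002") |>
      dplyr::mutate(path_id = "p3")
  )
  ch <- cohort(tr)
  metrics <- validate_paths(ch) |>
    dplyr::mutate(ui = c(1, 2, 3), nearest_neighbour_id = NA_character_,
                  p_norm = 2)
  s <- summarize_sessions(ch, metrics)
  expect_equal(s$mean_uniqueness, 2)
  expect_equal(s$fluency, 3)

  # metrics missing a session -> error naming it
  ch2 <- simulate_cohort(generator_config(n_agents = 2, seed = 32))
  m2 <- score_paths(ch2)
  expect_error(
    summarize_sessions(ch2, dplyr::filter(m2, participant_id != "a002")),
    "a002"
  )
})

test_that("correlate matches the closed-form estimator and rejects degenerate input", {
  d <- tibble::tibble(x = c(1, 2, 4, 5, 7), y = c(2, 1, 5, 4, 8))
  res <- correlate(d, x, y)
  r_hand <- sum((d$x - mean(d$x)) * (d$y - mean(d$y))) /
    sqrt(sum((d$x - mean(d$x))^2) * sum((d$y - mean(d$y))^2))
  expect_equal(res$estimate, r_hand, tolerance = 1e-12)
  expect_equal(res$df, 3)

  expect_equal(correlate(d, x, x)$estimate, 1)
  expect_error(correlate(tibble::tibble(x = 1:5, y = rep(2, 5)), x, y),
               "zero variance")
  expect_error(correlate(d[1:2, ], x, y), "at least 3")

  withr::with_seed(1, {
    big <- tibble::tibble(x = rnorm(500), y = rnorm(500))
  })
  expect_lt(abs(correlate(big, x, y)$estimate), 0.12)
})

test_that("partial correlation matches the recursive formula and its edge cases", {
  withr::with_seed(2, {
    d <- tibble::tibble(z = rnorm(60))
    d$x <- 0.5 * d$z + rnorm(60)
    d$y <- -0.3 * d$z + rnorm(60)
  })
  got <- partial_correlate(d, x, y, controls = z)
  r_xy <- cor(d$x, d$y); r_xz <- cor(d$x, d$z); r_yz <- cor(d$y, d$z)
  want <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  expect_equal(got$estimate, want, tolerance = 1e-10)
  expect_equal(got$df, 57)

  # empty control set reduces exactly to the plain correlation
  plain <- correlate(d, x, y)
  reduced <- partial_correlate(d, x, y, controls = c())
  expect_equal(reduced$estimate, plain$estimate)
  expect_equal(reduced$df, plain$df)

  # an uncorrelated control barely moves the estimate
  withr::with_seed(3, d$w <- rnorm(60))
  near <- partial_correlate(d, x, y, controls = w)
  expect_lt(abs(near$estimate - plain$estimate), 0.05)

  # y identical to the control: nothing left to correlate
  d$yc <- d$z
  gone <- partial_correlate(d, x, yc, controls = z)
  expect_equal(gone$estimate, 0)
  expect_equal(gone$p.value, 1)

  d$z2 <- 2 * d$z
  expect_error(partial_correlate(d, x, y, controls = c(z, z2)), "collinear")
})

test_that("the overlapping-correlation z test matches its formula and symmetries", {
  expect_equal(compare_correlations(0.5, 0.5, 0.3, 50)$statistic, 0)
  a <- compare_correlations(0.6, 0.2, 0.3, 80)
  b <- compare_correlations(0.2, 0.6, 0.3, 80)
  expect_equal(a$statistic, -b$statistic, tolerance = 1e-12)

  # frozen hand computation of the Meng-Rosenthal-Rubin statistic
  r_ab <- 0.56; r_ac <- -0.38; r_bc <- -0.62; n <- 96
  rbar2 <- (r_ab^2 + r_ac^2) / 2
  f <- min((1 - r_bc) / (2 * (1 - rbar2)), 1)
  h <- (1 - f * rbar2) / (1 - rbar2)
  z_hand <- (atanh(r_ab) - atanh(r_ac)) * sqrt((n - 3) / (2 * (1 - r_bc) * h))
  got <- compare_correlations(r_ab, r_ac, r_bc, n)
  expect_equal(got$statistic, z_hand, tolerance = 1e-12)

  naive <- compare_correlations(r_ab, r_ac, r_bc, n, dependent = FALSE)
  z_naive <- (atanh(r_ab) - atanh(r_ac)) / sqrt(2 / (n - 3))
  expect_equal(naive$statistic, z_naive, tolerance = 1e-12)

  expect_error(compare_correlations(1, 0.5, 0.3, 50), "strictly within")
  expect_error(compare_correlations(0.5, 0.4, 0.3, 3), "n must be")
})

test_that("paired comparison handles shifts, transforms and degenerate designs", {
  s <- tibble::tibble(
    participant_id = rep(sprintf("a%02d", 1:12), each = 2),
    condition = rep(c("ON", "OFF"), 12),
    fluency = rep(c(30, 22), 12) + rep(rnorm(12, sd = 0), each = 2)
  )
  # identical values in both conditions -> zero-variance flag, not Inf
  same <- dplyr::mutate(s, fluency = 25)
  expect_warning(res0 <- paired_compare(same, fluency), "zero-variance")
  expect_equal(res0$estimate, 0)
  expect_true(is.na(res0$statistic))

  withr::with_seed(4, {
    noisy <- dplyr::mutate(s, fluency = fluency + rnorm(24, sd = 2))
  })
  res <- paired_compare(noisy, fluency, conditions = c("ON", "OFF"),
                        transform = "none")
  expect_gt(res$estimate, 0)
  expect_lt(res$p.value, 0.001)
  expect_equal(res$n_pairs, 12)
  # matches the base paired t test directly
  wide <- tidyr::pivot_wider(noisy, names_from = condition,
                             values_from = fluency)
  tt <- t.test(wide$ON, wide$OFF, paired = TRUE)
  expect_equal(res$statistic, unname(tt$statistic))

  broken <- dplyr::filter(noisy, !(participant_id == "a03" & condition == "OFF"))
  expect_error(paired_compare(broken, fluency), "a03")

  # log transform applied automatically to clearly skewed positive data
  withr::with_seed(5, {
    skew <- dplyr::mutate(s, fluency = exp(rnorm(24, mean = 1 + (condition == "ON"))))
  })
  auto <- paired_compare(skew, fluency)
  expect_equal(auto$transform, "log")
})

test_that("the trial-level mixed model recovers a null and respects the refit contract", {
  cfg <- generator_config(
    n_agents = 12, seed = 41,
    condition_effects = list(ON = list())  # no condition effect at all
  )
  ch <- simulate_cohort(cfg, design = "ON_OFF_crossover")
  tab <- path_level_table(ch, score_paths(ch))
  fit <- tradeoff_mixed_model(tab, condition_ref = "OFF")
  cond <- fit$condition_effect
  expect_equal(cond$term, "conditionON")
  # null effect: estimate within a wide sampling band of zero
  expect_lt(abs(cond$statistic), 4)

  # duplicating every row: the within-participant (trial-level) terms keep
  # their estimates and gain precision; participant-level terms may move a
  # little because the variance components re-apportion
  fit2 <- suppressMessages(
    tradeoff_mixed_model(dplyr::bind_rows(tab, tab), condition_ref = "OFF"))
  t1 <- tidy(fit); t2 <- tidy(fit2)
  trial_terms <- c("duration_s", "conditionON")
  i1 <- match(trial_terms, t1$term); i2 <- match(trial_terms, t2$term)
  expect_equal(t2$estimate[i2], t1$estimate[i1], tolerance = 0.05)
  expect_true(all(t2$std.error[i2] < t1$std.error[i1]))

  g <- glance(fit)
  expect_equal(g$n_participants, 12)
  expect_equal(g$nobs, nrow(tab))

  expect_error(
    suppressWarnings(
      tradeoff_mixed_model(dplyr::filter(tab, condition == "ON"))),
    "at least 2 conditions")
})

test_that("the motivation regression returns one coefficient per measure", {
  ch <- simulate_cohort(generator_config(n_agents = 8, seed = 42))
  m <- score_paths(ch)
  d <- session_diversity(ch, seed = 6)
  s <- summarize_sessions(ch, m, d)
  co <- motivation_glm(s)
  expect_setequal(
    co$term,
    c("(Intercept)", "fluency", "mean_uniqueness", "hull_area")
  )
  expect_true(all(co$p.value >= 0 & co$p.value <= 1))
})
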