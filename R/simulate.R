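#' Parameters of one simulated agent
#'
#' An agent is a simulated participant whose drawn paths have controllable
#' shape dispersion (how unusual their paths are), drawing speed, a time
#' cost of unusualness (which mechanically induces the uniqueness-fluency
#' trade-off under the fixed session budget), optional rest tremor, a
#' motivation score, and per-condition multiplicative effects.
#'
#' @param dispersion Lateral spread sigma (mm) of the path-shape control
#'   points about the straight chord.
#' @param speed Drawing speed along the path, mm/s.
#' @param uniqueness_cost Extra seconds of path time per mm of the path's
#'   realized dispersion draw — the price of drawing an unusual path.
#' @param tremor_amplitude Lateral tremor amplitude, mm (default 0).
#' @param tremor_frequency Tremor frequency, Hz (default 4).
#' @param motivation Arbitrary-scale motivation score carried as a
#'   covariate.
#' @param condition_effects Named list of per-condition multipliers, each a
#'   list with any of `speed`, `dispersion`, `free_uniqueness`. `speed` and
#'   `dispersion` scale the corresponding agent parameter;
#'   `free_uniqueness` divides the time cost of dispersion, raising
#'   uniqueness attainable at a fixed path duration (the residual drug
#'   effect the trial-level mixed model is designed to detect).
#' @param seed Optional per-agent seed.
#' @return An object of class `og_agent`.
#' @export
agent_params <- function(dispersion = 12, speed = 130,
                         uniqueness_cost = 0.35, tremor_amplitude = 0,
                         tremor_frequency = 4, motivation = 0,
                         condition_effects = list(), seed = NULL) {
  stopifnot(dispersion >= 0, speed > 0, tremor_frequency > 0,
            uniqueness_cost >= 0, tremor_amplitude >= 0)
  structure(
    list(
      dispersion = dispersion, speed = speed,
      uniqueness_cost = uniqueness_cost,
      tremor_amplitude = tremor_amplitude,
      tremor_frequency = tremor_frequency,
      motivation = motivation,
      condition_effects = condition_effects,
      seed = seed
    ),
    class = "og_agent"
  )
}

condition_multipliers <- function(agent, condition) {
  eff <- agent$condition_effects[[condition %||% "none"]]
  list(
    speed = eff$speed %||% 1,
    dispersion = eff$dispersion %||% 1,
    free_uniqueness = eff$free_uniqueness %||% 1
  )
}

#' Cohort generator configuration
#'
#' Population-level settings for [simulate_cohort()]. The defaults are the
#' package's reference study conditions: 96 agents drawing on a 60 Hz
#' touchscreen under a 240 s budget, log-normal dispersion (median 12 mm)
#' and speed (median 130 mm/s) populations, a 0.35 s/mm time cost of
#' dispersion, 1.5 s inter-path gaps, and a latent motivation factor that
#' raises speed and lowers dispersion (so motivated agents are fluent while
#' apathetic agents draw fewer, more unusual paths). The ON/drug condition
#' effect raises speed (x1.25), lowers dispersion (x0.75) and raises
#' uniqueness-at-fixed-duration (x1.3).
#'
#' @param n_agents Number of simulated participants (default 96).
#' @param geometry A [task_geometry()].
#' @param sampling_rate Touch sampling rate in Hz (>= 30; default 60).
#' @param dispersion_meanlog,dispersion_sdlog Log-normal population of
#'   dispersion sigma (mm).
#' @param speed_meanlog,speed_sdlog Log-normal population of drawing speed
#'   (mm/s).
#' @param motivation_link Loading of the latent motivation factor on
#'   (minus) log dispersion, in (0, 1).
#' @param speed_motivation_link Loading of motivation on log speed.
#' @param uniqueness_cost Seconds of path time per mm of dispersion draw.
#' @param inter_path_gap Mean pause between consecutive paths, s.
#' @param gap_jitter_sd SD of the per-path gap jitter, s.
#' @param tremor_amplitude,tremor_frequency Population tremor (default none).
#' @param condition_effects Named list of per-condition multiplier lists
#'   (see [agent_params()]).
#' @param seed Master seed; the full cohort is reproducible from it.
#' @return An object of class `og_generator_config`.
#' @export
generator_config <- function(n_agents = 96, geometry = task_geometry(),
                             sampling_rate = 60,
                             dispersion_meanlog = log(12),
                             dispersion_sdlog = 0.5,
                             speed_meanlog = log(130), speed_sdlog = 0.25,
                             motivation_link = 0.6,
                             speed_motivation_link = 0.4,
                             uniqueness_cost = 0.35,
                             inter_path_gap = 1.5, gap_jitter_sd = 0.3,
                             tremor_amplitude = 0, tremor_frequency = 4,
                             condition_effects = list(
                               ON = list(speed = 1.25, dispersion = 0.75,
                                         free_uniqueness = 1.3),
                               drug = list(speed = 1.25, dispersion = 0.75,
                                           free_uniqueness = 1.3)
                             ),
                             seed = 1L) {
  stopifnot(is_count(n_agents), n_agents >= 1,
            is_scalar_number(sampling_rate), sampling_rate >= 30,
            inherits(geometry, "task_geometry"))
  structure(
    as.list(environment()),
    class = "og_generator_config"
  )
}

# Composite cubic spline from start to end through 3 interior control
# points with lateral offsets; returns fine polyline + arc length.
sim_path_shape <- function(from, to, offsets, n_fine = 257) {
  chord <- to - from
  len <- sqrt(sum(chord^2))
  u_hat <- chord / len
  perp <- c(-u_hat[2], u_hat[1])
  fr <- c(0, 0.25, 0.5, 0.75, 1)
  off <- c(0, offsets, 0)
  px <- from[1] + fr * chord[1] + off * perp[1]
  py <- from[2] + fr * chord[2] + off * perp[2]
  uu <- seq(0, 1, length.out = n_fine)
  fx <- stats::splinefun(fr, px, method = "natural")
  fy <- stats::splinefun(fr, py, method = "natural")
  x <- fx(uu)
  y <- fy(uu)
  s <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  list(x = x, y = y, s = s, length = s[length(s)], perp = perp)
}

# Sample a shape at constant arc speed over `duration`, add tremor, stamp
# times. Returns plain vectors (t relative to path onset) to keep the
# per-path overhead low; callers assemble tibbles once per session.
sim_path_samples <- function(shape, duration, sampling_rate,
                             tremor_amplitude = 0, tremor_frequency = 4) {
  t <- seq(0, duration, by = 1 / sampling_rate)
  if (t[length(t)] < duration - 1e-9) t <- c(t, duration)
  s_t <- pmin(pmax(shape$length * t / duration, 0), shape$length)
  x <- approx(shape$s, shape$x, xout = s_t, ties = "ordered")$y
  y <- approx(shape$s, shape$y, xout = s_t, ties = "ordered")$y
  if (tremor_amplitude > 0) {
    wob <- tremor_amplitude * sin(2 * pi * tremor_frequency * t)
    x <- x + wob * shape$perp[1]
    y <- y + wob * shape$perp[2]
  }
  list(t = t, x = x, y = y, n = length(t))
}

# Draw one option-generation path for an agent under a condition.
# Consumes the current RNG stream. Returns samples + bookkeeping.
sim_one_path <- function(agent, geom, condition = NULL,
                         sampling_rate = 60, duration = NULL,
                         target = NULL, dispersion = NULL) {
  mult <- condition_multipliers(agent, condition)
  sigma <- (dispersion %||% agent$dispersion) * mult$dispersion
  speed <- agent$speed * mult$speed
  from <- geom$start_center
  to <- target %||% geom$end_center
  side <- sample(c(-1, 1), 1)
  mags <- abs(rnorm(3, 0, max(sigma, 1e-12)))
  if (sigma == 0) mags <- rep(0, 3)
  offsets <- side * mags
  shape <- sim_path_shape(from, to, offsets)
  disp_draw <- mean(mags)
  think <- agent$uniqueness_cost * disp_draw / mult$free_uniqueness
  dur <- duration %||% (shape$length / speed + think)
  samples <- sim_path_samples(shape, dur, sampling_rate,
                              agent$tremor_amplitude,
                              agent$tremor_frequency)
  list(samples = samples, duration = dur, length = shape$length,
       disp_draw = disp_draw)
}

#' Simulate a single drawn path
#'
#' Builds one smooth synthetic path from the start circle to the goal
#' circle: a composite cubic spline whose three interior control points are
#' laterally offset from the straight chord by draws with scale
#' `dispersion` (mirror side chosen by a fair coin), time-stamped at
#' constant arc speed, with optional sinusoidal lateral tremor. Identical
#' seeds give bit-identical trajectories.
#'
#' @param agent An [agent_params()] object.
#' @param geometry A [task_geometry()].
#' @param path_index Index used to label the path (`p001`, ...).
#' @param condition Condition label whose effects to apply (or `NULL`).
#' @param sampling_rate Samples per second (default 60).
#' @param duration Optional total path duration in seconds; defaults to
#'   arc length / speed plus the dispersion time cost.
#' @param seed Optional seed for reproducibility of this single path.
#' @return A trajectory tibble for one path (columns `path_id`,
#'   `sample_index`, `t_s`, `x_mm`, `y_mm`), with attributes `duration`,
#'   `length` and `disp_draw`.
#' @export
simulate_path <- function(agent, geometry, path_index = 1,
                          condition = NULL, sampling_rate = 60,
                          duration = NULL, seed = NULL) {
  stopifnot(inherits(agent, "og_agent"), inherits(geometry, "task_geometry"))
  run <- function() {
    sim_one_path(agent, geometry, condition = condition,
                 sampling_rate = sampling_rate, duration = duration)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  s <- res$samples
  out <- tibble(path_id = sprintf("p%03d", path_index),
                sample_index = seq_len(s$n), t_s = s$t,
                x_mm = s$x, y_mm = s$y)
  attr(out, "duration") <- res$duration
  attr(out, "length") <- res$length
  attr(out, "disp_draw") <- res$disp_draw
  out
}

#' Simulate one option-generation session
#'
#' Draws paths sequentially under the session time budget: each path's
#' duration is its arc length divided by the (condition-adjusted) speed
#' plus `uniqueness_cost` times the path's realized dispersion draw
#' (divided by any `free_uniqueness` condition multiplier), and paths are
#' separated by jittered inter-path gaps. Generation stops when the next
#' path would overrun the budget, so drawing more-dispersed paths
#' mechanically lowers fluency — the uniqueness-fluency trade-off emerges
#' from the generative process rather than being painted on.
#'
#' @param agent An [agent_params()].
#' @param geometry A [task_geometry()]; its `time_limit` is the budget.
#' @param participant_id,session_index,condition Session labels.
#' @param sampling_rate Samples per second (default 60).
#' @param inter_path_gap Mean pause between paths, s (default 1.5).
#' @param gap_jitter_sd SD of gap jitter, s (default 0.3).
#' @param seed Optional seed.
#' @return A trajectory tibble for the session, with attribute `"truth"`:
#'   a per-path tibble of generative duration, arc length and dispersion
#'   draw.
#' @export
simulate_session <- function(agent, geometry, participant_id = "a01",
                             session_index = 1L, condition = "none",
                             sampling_rate = 60, inter_path_gap = 1.5,
                             gap_jitter_sd = 0.3, seed = NULL) {
  stopifnot(inherits(agent, "og_agent"), inherits(geometry, "task_geometry"))
  run <- function() {
    clock <- 0
    rows <- list()
    truth <- list()
    k <- 0L
    repeat {
      res <- sim_one_path(agent, geometry, condition = condition,
                          sampling_rate = sampling_rate)
      if (clock + res$duration > geometry$time_limit) break
      k <- k + 1L
      pid <- sprintf("p%03d", k)
      s <- res$samples
      rows[[k]] <- list(path_id = rep(pid, s$n),
                        sample_index = seq_len(s$n),
                        t_s = s$t + clock, x_mm = s$x, y_mm = s$y)
      truth[[k]] <- c(duration = res$duration, length = res$length,
                      disp_draw = res$disp_draw, onset = clock)
      gap <- max(0.2, inter_path_gap + rnorm(1, 0, gap_jitter_sd))
      clock <- clock + res$duration + gap
      if (clock >= geometry$time_limit) break
    }
    list(rows = rows, truth = truth)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  pull_all <- function(field) {
    do.call(c, lapply(res$rows, `[[`, field))
  }
  out <- tibble(
    participant_id = participant_id,
    session_index = as.integer(session_index),
    condition = condition,
    task_kind = "option_generation",
    path_id = if (length(res$rows)) pull_all("path_id") else character(),
    sample_index = if (length(res$rows)) pull_all("sample_index") else integer(),
    t_s = if (length(res$rows)) pull_all("t_s") else double(),
    x_mm = if (length(res$rows)) pull_all("x_mm") else double(),
    y_mm = if (length(res$rows)) pull_all("y_mm") else double()
  )
  truth <- as_tibble(do.call(rbind, res$truth))
  if (nrow(truth) > 0) {
    truth$path_id <- sprintf("p%03d", seq_len(nrow(truth)))
  }
  attr(out, "truth") <- truth
  out
}

#' Simulate a control-task session
#'
#' Emulates the three control tasks used alongside option generation:
#' `motor_execution` (exactly 10 near-straight lines from the start circle
#' to the goal circle, drawn as fast as the agent can), `cued_action`
#' (straight lines to computer-cued targets appearing one at a time at the
#' task distance and a uniformly random angle within ±90° of vertical,
#' under a 90 s budget) and `option_selection` (straight lines to
#' self-chosen targets among 24 equally spaced locations on an arc at the
#' task distance, 90 s budget).
#'
#' @param agent An [agent_params()].
#' @param geometry A [task_geometry()].
#' @param task_kind One of `"motor_execution"`, `"cued_action"`,
#'   `"option_selection"`.
#' @param participant_id,session_index,condition Session labels.
#' @param sampling_rate Samples per second.
#' @param time_budget Budget for the cued/selection tasks, s (default 90).
#' @param inter_path_gap Pause between paths, s (default 1).
#' @param seed Optional seed.
#' @return A trajectory tibble; for the target tasks the attribute
#'   `"targets"` records each path's target location and angle.
#' @export
simulate_control_task <- function(agent, geometry,
                                  task_kind = c("motor_execution",
                                                "cued_action",
                                                "option_selection"),
                                  participant_id = "a01",
                                  session_index = 1L, condition = "none",
                                  sampling_rate = 60, time_budget = 90,
                                  inter_path_gap = 1, seed = NULL) {
  task_kind <- match.arg(task_kind)
  stopifnot(inherits(agent, "og_agent"), inherits(geometry, "task_geometry"))
  start <- geometry$start_center
  sep <- geometry$separation
  straight_agent <- agent_params(
    dispersion = 0.5, speed = agent$speed, uniqueness_cost = 0,
    tremor_amplitude = agent$tremor_amplitude,
    tremor_frequency = agent$tremor_frequency,
    condition_effects = agent$condition_effects
  )
  arc_targets <- function(theta_deg) {
    # angle measured from vertical (the start->goal direction)
    th <- theta_deg * pi / 180
    cbind(start[1] + sep * sin(th), start[2] + sep * cos(th))
  }
  run <- function() {
    rows <- list()
    targets <- list()
    clock <- 0
    k <- 0L
    repeat {
      if (task_kind == "motor_execution") {
        if (k >= 10) break
        target <- geometry$end_center
        angle <- 0
      } else if (task_kind == "cued_action") {
        angle <- runif(1, -90, 90)
        target <- drop(arc_targets(angle))
      } else {
        slots <- seq(-90, 90, length.out = 24)
        angle <- slots[sample.int(24, 1)]
        target <- drop(arc_targets(angle))
      }
      res <- sim_one_path(straight_agent, geometry, condition = condition,
                          sampling_rate = sampling_rate, target = target)
      if (task_kind != "motor_execution" &&
          clock + res$duration > time_budget) break
      k <- k + 1L
      pid <- sprintf("p%03d", k)
      s <- res$samples
      rows[[k]] <- tibble(path_id = pid, sample_index = seq_len(s$n),
                          t_s = s$t + clock, x_mm = s$x, y_mm = s$y)
      targets[[k]] <- tibble(path_id = pid, angle_deg = angle,
                             target_x = target[1], target_y = target[2],
                             duration = res$duration)
      clock <- clock + res$duration + inter_path_gap
    }
    list(rows = rows, targets = targets)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out <- bind_rows(res$rows) |>
    mutate(participant_id = participant_id,
           session_index = as.integer(session_index),
           condition = condition,
           task_kind = task_kind) |>
    select(all_of(TRAJECTORY_COLS))
  attr(out, "targets") <- bind_rows(res$targets)
  out
}

#' Simulate a cohort of agents
#'
#' Draws a population of agents from the configured distributions and
#' simulates their sessions under one of three designs:
#' `"single_session"` (one session per agent), `"ON_OFF_crossover"` or
#' `"drug_placebo_crossover"` (two counterbalanced sessions per agent with
#' the configured condition effects applied to the ON/drug session).
#' A latent motivation factor links the population draws: motivated agents
#' are faster and less disperse, apathetic agents slower and more disperse.
#' Everything is reproducible from the master seed.
#'
#' @param config An [generator_config()].
#' @param design Study design (see above).
#' @return An `og_cohort` whose covariate table carries `motivation` and
#'   `apathy` per session and whose attribute `"agents"` records the true
#'   generative parameters per agent.
#' @export
simulate_cohort <- function(config = generator_config(),
                            design = c("single_session", "ON_OFF_crossover",
                                       "drug_placebo_crossover")) {
  stopifnot(inherits(config, "og_generator_config"))
  design <- match.arg(design)
  conditions <- switch(design,
    single_session = "none",
    ON_OFF_crossover = c("ON", "OFF"),
    drug_placebo_crossover = c("drug", "placebo")
  )
  geom <- config$geometry
  out <- withr::with_seed(config$seed, {
    n <- config$n_agents
    z_m <- rnorm(n)                      # latent motivation factor
    rho <- config$motivation_link
    eps_s <- rnorm(n)
    eps_v <- rnorm(n)
    sigma <- exp(config$dispersion_meanlog +
                 config$dispersion_sdlog *
                   (-rho * z_m + sqrt(1 - rho^2) * eps_s))
    speed <- exp(config$speed_meanlog +
                 config$speed_sdlog *
                   (config$speed_motivation_link * z_m +
                    sqrt(1 - config$speed_motivation_link^2) * eps_v))
    ids <- sprintf("a%03d", seq_len(n))
    traj <- list()
    covs <- list()
    agents <- tibble(
      participant_id = ids, dispersion = sigma, speed = speed,
      motivation = z_m, apathy = -z_m
    )
    for (i in seq_len(n)) {
      agent <- agent_params(
        dispersion = sigma[i], speed = speed[i],
        uniqueness_cost = config$uniqueness_cost,
        tremor_amplitude = config$tremor_amplitude,
        tremor_frequency = config$tremor_frequency,
        motivation = z_m[i],
        condition_effects = config$condition_effects
      )
      # counterbalanced condition order across agents
      conds <- if (length(conditions) == 2 && i %% 2 == 0) {
        rev(conditions)
      } else {
        conditions
      }
      for (s in seq_along(conds)) {
        traj[[length(traj) + 1L]] <- simulate_session(
          agent, geom,
          participant_id = ids[i], session_index = s,
          condition = conds[s], sampling_rate = config$sampling_rate,
          inter_path_gap = config$inter_path_gap,
          gap_jitter_sd = config$gap_jitter_sd
        )
        covs[[length(covs) + 1L]] <- tibble(
          participant_id = ids[i], session_index = s,
          covariate_name = c("motivation", "apathy"),
          value = c(z_m[i], -z_m[i])
        )
      }
    }
    list(traj = bind_rows(traj), covs = bind_rows(covs), agents = agents)
  })
  ch <- cohort(
    out$traj, geometry = geom, covariates = out$covs,
    provenance = sprintf("simulate_cohort(design = %s, n_agents = %d, seed = %d)",
                         design, config$n_agents, config$seed)
  )
  attr(ch, "agents") <- out$agents
  ch
}
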