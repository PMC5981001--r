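#' Validate paths against the task geometry
#'
#' A path is valid when its first sample lies within `endpoint_tolerance`
#' (inclusive: "within 21 mm" is read as \eqn{\le} 21 mm) of the start-circle
#' center and its last sample within the tolerance of the goal-circle
#' center. For the externally cued and option-selection control tasks the
#' paths end at arbitrary targets, so only the start-side check applies.
#' Invalid paths are never dropped here; downstream metrics exclude them by
#' the `valid` flag so the record stays auditable.
#'
#' @param trajectories Trajectory table (or an `og_cohort`).
#' @param geometry A [task_geometry()]; taken from the cohort when omitted.
#' @return A tibble with one row per path: identifiers, `valid`, `reason`
#'   (`NA`, `"start"`, `"end"` or `"start+end"`), `onset_s`, `duration_s`,
#'   `n_samples`.
#' @export
validate_paths <- function(trajectories, geometry = NULL) {
  if (inherits(trajectories, "og_cohort")) {
    geometry <- geometry %||% trajectories$geometry
    trajectories <- trajectories$trajectories
  }
  stopifnot(inherits(geometry, "task_geometry"))
  assert_columns(trajectories, TRAJECTORY_COLS, "trajectory table")
  tol <- geometry$endpoint_tolerance
  sc <- geometry$start_center
  ec <- geometry$end_center
  trajectories |>
    group_by(participant_id, session_index, condition, task_kind, path_id) |>
    arrange(sample_index, .by_group = TRUE) |>
    summarise(
      onset_s = min(t_s),
      duration_s = max(t_s) - min(t_s),
      n_samples = n(),
      .d_start = sqrt((first(x_mm) - sc[1])^2 + (first(y_mm) - sc[2])^2),
      .d_end = sqrt((last(x_mm) - ec[1])^2 + (last(y_mm) - ec[2])^2),
      .groups = "drop"
    ) |>
    mutate(
      .end_checked = !(task_kind %in% c("cued_action", "option_selection")),
      .bad_start = .data$.d_start > tol,
      .bad_end = .data$.end_checked & .data$.d_end > tol,
      valid = !.data$.bad_start & !.data$.bad_end,
      reason = case_when(
        .data$.bad_start & .data$.bad_end ~ "start+end",
        .data$.bad_start ~ "start",
        .data$.bad_end ~ "end",
        .default = NA_character_
      )
    ) |>
    select(participant_id, session_index, condition, task_kind, path_id,
           valid, reason, onset_s, duration_s, n_samples)
}

#' Smooth trajectories with a centered time-based moving average
#'
#' Replaces each coordinate by the mean of all samples within ±`window`/2
#' seconds of its timestamp (truncated at the path ends); timestamps are
#' unchanged. The window is time-based rather than sample-count-based so the
#' filter behaves identically under irregular sampling. A 250 ms boxcar has
#' its first spectral null at 4 Hz (\eqn{\mathrm{sinc}(f w) = 0} at
#' \eqn{f = 1/w}), which is what makes it the standard control for ~4 Hz
#' Parkinsonian tremor.
#'
#' @param trajectories Trajectory table (or an `og_cohort`, in which case the
#'   smoothed cohort is returned).
#' @param window Full window width in seconds (default 0.25).
#' @return The input with `x_mm`, `y_mm` smoothed.
#' @export
smooth_trajectories <- function(trajectories, window = 0.25) {
  if (inherits(trajectories, "og_cohort")) {
    trajectories$trajectories <-
      smooth_trajectories(trajectories$trajectories, window)
    return(trajectories)
  }
  stopifnot(is_scalar_number(window), window > 0)
  assert_columns(trajectories, c("path_id", "t_s", "x_mm", "y_mm"),
                 "trajectory table")
  pieces <- split_paths(trajectories)
  out <- lapply(pieces, function(p) {
    if (nrow(p) < 2) {
      abort(sprintf("cannot smooth single-sample path '%s'", p$path_id[1]))
    }
    p <- p[order(p$t_s, p$sample_index %||% seq_len(nrow(p))), ]
    t <- p$t_s
    half <- window / 2 + 1e-12  # inclusive boundary under float noise
    lo <- findInterval(t - half, t, left.open = TRUE) + 1
    hi <- findInterval(t + half, t)
    nwin <- hi - lo + 1
    csx <- c(0, cumsum(p$x_mm))
    csy <- c(0, cumsum(p$y_mm))
    p$x_mm <- (csx[hi + 1] - csx[lo]) / nwin
    p$y_mm <- (csy[hi + 1] - csy[lo]) / nwin
    p
  })
  bind_rows(out)
}

#' Cumulative arc-length profile of each path
#'
#' Adds `s_mm`, the cumulative Euclidean distance along the polyline up to
#' each sample (`s_mm` is 0 at the first sample; consecutive duplicate
#' positions contribute zero length).
#'
#' @param trajectories Trajectory table.
#' @return The table with an `s_mm` column appended.
#' @export
arc_length_profile <- function(trajectories) {
  assert_columns(trajectories, c("path_id", "x_mm", "y_mm"),
                 "trajectory table")
  pieces <- split_paths(trajectories)
  out <- lapply(pieces, function(p) {
    s <- c(0, cumsum(sqrt(diff(p$x_mm)^2 + diff(p$y_mm)^2)))
    if (s[length(s)] <= 0) {
      abort(sprintf("degenerate path '%s': zero total length", p$path_id[1]),
            class = "og_degenerate_path")
    }
    p$s_mm <- s
    p
  })
  bind_rows(out)
}

#' Resample paths to arc-length-uniform coordinates
#'
#' Re-parameterizes each path by distance travelled along it and linearly
#' interpolates the coordinates at `n_resample` equally spaced arc lengths
#' \eqn{k L/(n-1)}, \eqn{k = 0, \dots, n-1}. Only sample positions are used
#' — timestamps never enter — so the result is bit-identical for the same
#' polyline drawn at any speed. First and last resampled points equal the
#' first and last source samples exactly.
#'
#' @param trajectories Trajectory table (or `og_cohort`).
#' @param n_resample Number of arc-length-uniform points per path
#'   (default 200).
#' @return A tibble with one row per resampled point: path identifiers,
#'   `point_index` (1-based), `s_mm`, `x_mm`, `y_mm`, `total_length_mm`.
#' @export
resample_paths <- function(trajectories, n_resample = 200) {
  if (inherits(trajectories, "og_cohort")) {
    trajectories <- trajectories$trajectories
  }
  stopifnot(is_count(n_resample), n_resample >= 2)
  assert_columns(trajectories, c("participant_id", "session_index",
                                 "condition", "path_id", "x_mm", "y_mm"),
                 "trajectory table")
  pieces <- split_paths(trajectories)
  n_paths <- length(pieces)
  xs <- vector("list", n_paths)
  ys <- vector("list", n_paths)
  ss <- vector("list", n_paths)
  lens <- numeric(n_paths)
  meta <- vector("list", n_paths)
  for (k in seq_len(n_paths)) {
    p <- pieces[[k]]
    dd <- dedupe_points(p$x_mm, p$y_mm)
    if (length(dd$x) < 2) {
      abort(sprintf("degenerate path '%s': zero total length", p$path_id[1]),
            class = "og_degenerate_path")
    }
    s <- c(0, cumsum(sqrt(diff(dd$x)^2 + diff(dd$y)^2)))
    L <- s[length(s)]
    targets <- seq(0, L, length.out = n_resample)
    x <- approx(s, dd$x, xout = targets, ties = "ordered")$y
    y <- approx(s, dd$y, xout = targets, ties = "ordered")$y
    # endpoints exact by contract
    x[1] <- dd$x[1]; y[1] <- dd$y[1]
    x[n_resample] <- dd$x[length(dd$x)]
    y[n_resample] <- dd$y[length(dd$y)]
    xs[[k]] <- x; ys[[k]] <- y; ss[[k]] <- targets
    lens[k] <- L
    meta[[k]] <- c(p$participant_id[1], as.character(p$session_index[1]),
                   p$condition[1], p$path_id[1])
  }
  mm <- do.call(rbind, meta)
  res <- tibble(
    participant_id = rep(mm[, 1], each = n_resample),
    session_index = rep(as.integer(mm[, 2]), each = n_resample),
    condition = rep(mm[, 3], each = n_resample),
    path_id = rep(mm[, 4], each = n_resample),
    point_index = rep.int(seq_len(n_resample), n_paths),
    s_mm = unlist(ss, use.names = FALSE),
    x_mm = unlist(xs, use.names = FALSE),
    y_mm = unlist(ys, use.names = FALSE),
    total_length_mm = rep(lens, each = n_resample)
  )
  attr(res, "n_resample") <- n_resample
  res
}

#' Add a sinusoidal lateral tremor to trajectories
#'
#' Adds `amplitude * sin(2 pi frequency (t - onset))` to the x-coordinate of
#' every path (onset = the path's first timestamp). Used to emulate ~4 Hz
#' Parkinsonian rest tremor on otherwise clean synthetic paths so the
#' smoothing control analysis can be exercised against a known ground truth.
#'
#' @param trajectories Trajectory table or `og_cohort`.
#' @param amplitude Tremor amplitude in mm (default 2).
#' @param frequency Tremor frequency in Hz (default 4).
#' @return The input with perturbed x-coordinates.
#' @export
add_tremor <- function(trajectories, amplitude = 2, frequency = 4) {
  if (inherits(trajectories, "og_cohort")) {
    trajectories$trajectories <-
      add_tremor(trajectories$trajectories, amplitude, frequency)
    return(trajectories)
  }
  stopifnot(is_scalar_number(amplitude), is_scalar_number(frequency),
            frequency > 0)
  trajectories |>
    group_by(participant_id, session_index, path_id) |>
    mutate(x_mm = x_mm + amplitude * sin(2 * pi * frequency * (t_s - min(t_s)))) |>
    ungroup()
}
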