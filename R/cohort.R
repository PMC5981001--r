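#' Construct a cohort of drawing sessions
#'
#' A cohort bundles a flat trajectory table (one row per touch sample), a
#' long covariate table, and the task geometry. The trajectory table has
#' columns `participant_id`, `session_index`, `condition`, `task_kind`,
#' `path_id`, `sample_index`, `t_s`, `x_mm`, `y_mm`; timestamps `t_s` are
#' seconds from session start, so a path's onset is its first timestamp and
#' its drawing duration is last minus first timestamp.
#'
#' @param trajectories Data frame of touch samples. Missing `condition` /
#'   `task_kind` columns are filled with `"none"` / `"option_generation"`.
#' @param geometry A [task_geometry()].
#' @param covariates Data frame with columns `participant_id`,
#'   `session_index`, `covariate_name`, `value` (long format), or `NULL`.
#' @param provenance Free-text note on where the data came from.
#'
#' @return An object of class `og_cohort`: a list with elements
#'   `trajectories`, `covariates`, `geometry`, `provenance`.
#' @seealso [read_cohort()], [write_cohort()], [validate_cohort()],
#'   [simulate_cohort()]
#' @export
cohort <- function(trajectories, geometry = task_geometry(),
                   covariates = NULL, provenance = "") {
  trajectories <- as_tibble(trajectories)
  if (!"condition" %in% names(trajectories)) trajectories$condition <- "none"
  if (!"task_kind" %in% names(trajectories)) {
    trajectories$task_kind <- "option_generation"
  }
  assert_columns(trajectories, TRAJECTORY_COLS, "trajectory table")
  trajectories <- trajectories[, union(TRAJECTORY_COLS,
                                       names(trajectories))]
  if (is.null(covariates)) {
    covariates <- tibble(
      participant_id = character(), session_index = integer(),
      covariate_name = character(), value = double()
    )
  }
  covariates <- as_tibble(covariates)
  assert_columns(
    covariates,
    c("participant_id", "session_index", "covariate_name", "value"),
    "covariate table"
  )
  out <- structure(
    list(
      trajectories = trajectories,
      covariates = covariates,
      geometry = geometry,
      provenance = provenance
    ),
    class = "og_cohort"
  )
  validate_cohort(out)
}

#' @export
print.og_cohort <- function(x, ...) {
  tr <- x$trajectories
  n_paths <- length(unique(og_key(tr)))
  n_sessions <- nrow(distinct(tr, participant_id, session_index))
  n_participants <- length(unique(tr$participant_id))
  cat("<og_cohort>\n")
  cat(sprintf("  %d participants, %d sessions, %d paths, %d samples\n",
              n_participants, n_sessions, n_paths, nrow(tr)))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Validate a cohort against the data-model invariants
#'
#' Checks, per path: at least two samples, non-decreasing timestamps,
#' positive polyline length after removal of consecutive duplicate points,
#' onsets within `[0, time_limit]`, and unique `sample_index` within a path.
#' All violations are collected and reported together (with path ids and the
#' first offending row number); nothing is silently dropped.
#'
#' @param x An `og_cohort`.
#' @return `x` invisibly if valid; otherwise an error of class
#'   `og_validation_error` listing every violation.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "og_cohort"))
  tr <- x$trajectories
  problems <- character()
  if (nrow(tr) > 0) {
    pieces <- split_paths(tr)
    row_of <- split(seq_len(nrow(tr)),
                    factor(og_key(tr), levels = unique(og_key(tr))))
    for (k in seq_along(pieces)) {
      p <- pieces[[k]]
      rows <- row_of[[k]]
      id <- sprintf("participant %s session %s path %s",
                    p$participant_id[1], p$session_index[1], p$path_id[1])
      if (nrow(p) < 2) {
        problems <- c(problems, sprintf(
          "%s (row %d): fewer than 2 samples", id, rows[1]))
        next
      }
      if (any(diff(p$t_s) < 0)) {
        bad <- which(diff(p$t_s) < 0)[1]
        problems <- c(problems, sprintf(
          "%s (row %d): non-monotonic timestamps", id, rows[bad + 1]))
      }
      dd <- dedupe_points(p$x_mm, p$y_mm)
      if (polyline_length(dd$x, dd$y) <= 0) {
        problems <- c(problems, sprintf(
          "%s (row %d): zero total path length", id, rows[1]))
      }
      if (anyDuplicated(p$sample_index)) {
        problems <- c(problems, sprintf(
          "%s (row %d): duplicated sample_index", id, rows[1]))
      }
      onset <- min(p$t_s)
      if (onset < 0 || onset > x$geometry$time_limit) {
        problems <- c(problems, sprintf(
          "%s (row %d): onset %.3f s outside [0, %.0f]",
          id, rows[1], onset, x$geometry$time_limit))
      }
    }
  }
  if (length(problems) > 0) {
    abort(
      c("cohort fails validation:", setNames(problems, rep("x", length(problems)))),
      class = "og_validation_error"
    )
  }
  invisible(x)
}

#' Read a cohort from its tabular files
#'
#' Reads the flat trajectory table (CSV, one row per touch sample) plus the
#' optional covariate table and geometry configuration, converts device
#' pixels to mm when needed, and validates every data-model invariant.
#' When `geometry`/`covariates` are `NULL`, companion files written by
#' [write_cohort()] (`<stem>_geometry.yml`, `<stem>_covariates.csv`) are
#' picked up automatically if present.
#'
#' If the trajectory file carries `x_px`/`y_px` instead of `x_mm`/`y_mm`,
#' coordinates are converted with the geometry's `pixels_per_mm` calibration.
#'
#' @param path CSV file with the trajectory table.
#' @param geometry A `task_geometry`, a geometry config file path, or `NULL`.
#' @param covariates Covariate CSV path, data frame, or `NULL`.
#' @param provenance Free-text provenance; defaults to the file path.
#' @return An `og_cohort`.
#' @export
read_cohort <- function(path, geometry = NULL, covariates = NULL,
                        provenance = NULL) {
  if (!file.exists(path)) abort(sprintf("trajectory file not found: %s", path))
  stem <- sub("\\.[^.]+$", "", path)
  if (is.null(geometry)) {
    gfile <- paste0(stem, "_geometry.yml")
    geometry <- if (file.exists(gfile)) read_geometry(gfile) else task_geometry()
  } else if (is.character(geometry)) {
    geometry <- read_geometry(geometry)
  }
  tr <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("session_index" %in% names(tr)) {
    tr$session_index <- as.integer(tr$session_index)
  }
  if ("sample_index" %in% names(tr)) {
    tr$sample_index <- as.integer(tr$sample_index)
  }
  if (!"x_mm" %in% names(tr) && "x_px" %in% names(tr)) {
    tr$x_mm <- tr$x_px / geometry$pixels_per_mm["x"]
    tr$y_mm <- tr$y_px / geometry$pixels_per_mm["y"]
    tr$x_px <- NULL
    tr$y_px <- NULL
  }
  if (is.null(covariates)) {
    cfile <- paste0(stem, "_covariates.csv")
    if (file.exists(cfile)) {
      covariates <- readr::read_csv(cfile, show_col_types = FALSE,
                                    progress = FALSE)
    }
  } else if (is.character(covariates)) {
    covariates <- readr::read_csv(covariates, show_col_types = FALSE,
                                  progress = FALSE)
  }
  if (!is.null(covariates) && "session_index" %in% names(covariates)) {
    covariates$session_index <- as.integer(covariates$session_index)
  }
  tr <- arrange(as_tibble(tr), participant_id, session_index, path_id,
                sample_index)
  cohort(tr, geometry = geometry, covariates = covariates,
         provenance = provenance %||% path)
}

#' Write a cohort to plain tabular files
#'
#' Writes the trajectory table to `path` (CSV, canonical column order), the
#' covariate table to `<stem>_covariates.csv` and the geometry to
#' `<stem>_geometry.yml`. Numeric fields use the shortest round-trippable
#' decimal representation, so `read_cohort(write_cohort(x))` reproduces `x`
#' exactly and two writes of the same cohort are byte-identical.
#'
#' @param x An `og_cohort`.
#' @param path Output CSV path for the trajectory table.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "og_cohort"))
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- sub("\\.[^.]+$", "", path)
  tr <- arrange(x$trajectories[, TRAJECTORY_COLS],
                participant_id, session_index, path_id, sample_index)
  readr::write_csv(tr, path, progress = FALSE)
  readr::write_csv(x$covariates, paste0(stem, "_covariates.csv"),
                   progress = FALSE)
  write_geometry(x$geometry, paste0(stem, "_geometry.yml"))
  invisible(path)
}

#' Pool several cohorts into one
#'
#' Concatenates the trajectory and covariate tables of cohorts sharing the
#' same task geometry, e.g. to compute uniqueness over a multi-study pool.
#'
#' @param ... `og_cohort` objects (or a single list of them).
#' @return An `og_cohort`.
#' @export
combine_cohorts <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && !inherits(xs[[1]], "og_cohort")) xs <- xs[[1]]
  stopifnot(length(xs) >= 1, all(vapply(xs, inherits, TRUE, "og_cohort")))
  if (length(xs) == 1) return(xs[[1]])
  g1 <- xs[[1]]$geometry
  for (x in xs[-1]) {
    if (!isTRUE(all.equal(x$geometry[names(x$geometry) != "pixels_per_mm"],
                          g1[names(g1) != "pixels_per_mm"]))) {
      abort("cohorts to pool must share the same task geometry")
    }
  }
  keys <- bind_rows(lapply(xs, function(x) {
    distinct(x$trajectories, participant_id, session_index)
  }))
  if (anyDuplicated(keys)) {
    abort("participant/session keys collide across pooled cohorts")
  }
  cohort(
    bind_rows(lapply(xs, `[[`, "trajectories")),
    geometry = g1,
    covariates = bind_rows(lapply(xs, `[[`, "covariates")),
    provenance = paste(vapply(xs, `[[`, "", "provenance"), collapse = " + ")
  )
}
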