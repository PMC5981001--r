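#' Task geometry for the drawing tasks
#'
#' Describes the on-screen layout of the option-generation task: two circles
#' vertically aligned on the screen, a validity tolerance around their
#' centers, and the session time budget. All lengths are millimetres; the
#' coordinate origin is the bottom-left screen corner with y increasing
#' upward, so the end (goal) circle has the larger y ("bottom circle" to
#' "top circle"). The defaults encode the standard task: centers 204 mm
#' apart, 13 mm circle radius, paths valid when they start and end within
#' 21 mm of the respective centers, and a 240 s drawing budget.
#'
#' @param start_center Numeric length-2, (x, y) of the start (bottom) circle
#'   center in mm.
#' @param end_center Numeric length-2, (x, y) of the goal (top) circle center
#'   in mm.
#' @param circle_radius Circle radius in mm.
#' @param endpoint_tolerance Validity tolerance in mm: a path is valid when
#'   its first sample lies within this distance of `start_center` and its
#'   last sample within this distance of `end_center` (inclusive).
#' @param time_limit Session time budget in seconds (240 s for option
#'   generation; the cued-action and option-selection control tasks use 90 s
#'   budgets at simulation time).
#' @param screen_width,screen_height Physical screen size in mm.
#' @param pixels_per_mm Named numeric, `c(x = , y = )`: screen calibration
#'   used to convert device pixels to mm on ingestion when a trajectory file
#'   carries `x_px`/`y_px` columns.
#'
#' @return An object of class `task_geometry`.
#' @examples
#' geom <- task_geometry()
#' geom$endpoint_tolerance
#' @export
task_geometry <- function(start_center = c(254.5, 41),
                          end_center = c(254.5, 245),
                          circle_radius = 13,
                          endpoint_tolerance = 21,
                          time_limit = 240,
                          screen_width = 509,
                          screen_height = 286,
                          pixels_per_mm = c(x = 1, y = 1)) {
  stopifnot(
    is.numeric(start_center), length(start_center) == 2,
    is.numeric(end_center), length(end_center) == 2,
    is_scalar_number(circle_radius), circle_radius > 0,
    is_scalar_number(endpoint_tolerance),
    is_scalar_number(time_limit),
    is_scalar_number(screen_width), screen_width > 0,
    is_scalar_number(screen_height), screen_height > 0
  )
  if (endpoint_tolerance < circle_radius) {
    abort("endpoint_tolerance must be >= circle_radius")
  }
  sep <- sqrt(sum((end_center - start_center)^2))
  if (sep <= 0) abort("start_center and end_center must be distinct")
  if (time_limit <= 0) abort("time_limit must be > 0")
  ppm <- c(x = unname(pixels_per_mm["x"] %||% pixels_per_mm[1]),
           y = unname(pixels_per_mm["y"] %||% pixels_per_mm[2]))
  structure(
    list(
      start_center = unname(as.numeric(start_center)),
      end_center = unname(as.numeric(end_center)),
      circle_radius = circle_radius,
      endpoint_tolerance = endpoint_tolerance,
      time_limit = time_limit,
      screen_width = screen_width,
      screen_height = screen_height,
      pixels_per_mm = ppm,
      separation = sep
    ),
    class = "task_geometry"
  )
}

#' @export
print.task_geometry <- function(x, ...) {
  cat("<task_geometry>\n")
  cat(sprintf("  start (%.1f, %.1f) mm -> end (%.1f, %.1f) mm  [separation %.1f mm]\n",
              x$start_center[1], x$start_center[2],
              x$end_center[1], x$end_center[2], x$separation))
  cat(sprintf("  circle radius %.1f mm, endpoint tolerance %.1f mm\n",
              x$circle_radius, x$endpoint_tolerance))
  cat(sprintf("  time limit %.0f s, screen %.0f x %.0f mm\n",
              x$time_limit, x$screen_width, x$screen_height))
  invisible(x)
}

# x-coordinate of the vertical task axis; the mirror reflection is about this
# line. Errors when the two circle centers are not vertically aligned.
geometry_axis_x <- function(geom) {
  stopifnot(inherits(geom, "task_geometry"))
  if (geom$start_center[1] != geom$end_center[1]) {
    abort(paste0(
      "mirror reflection requires a vertical task axis ",
      "(start and end centers sharing x)"
    ), class = "og_geometry_error")
  }
  geom$start_center[1]
}

#' Read or write a task geometry configuration file
#'
#' Geometry configurations are stored as YAML (or JSON) with the
#' [task_geometry()] fields; `pixels_per_mm_x`/`pixels_per_mm_y` carry the
#' screen calibration.
#'
#' @param path File path; format chosen by extension (`.json` for JSON,
#'   anything else is parsed as YAML).
#' @return `read_geometry()` returns a `task_geometry`; `write_geometry()`
#'   returns `path` invisibly.
#' @export
read_geometry <- function(path) {
  if (!file.exists(path)) abort(sprintf("geometry file not found: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  task_geometry(
    start_center = as.numeric(cfg$start_center %||% c(254.5, 41)),
    end_center = as.numeric(cfg$end_center %||% c(254.5, 245)),
    circle_radius = cfg$circle_radius %||% 13,
    endpoint_tolerance = cfg$endpoint_tolerance %||% 21,
    time_limit = cfg$time_limit %||% 240,
    screen_width = cfg$screen_width %||% 509,
    screen_height = cfg$screen_height %||% 286,
    pixels_per_mm = c(x = cfg$pixels_per_mm_x %||% 1,
                      y = cfg$pixels_per_mm_y %||% 1)
  )
}

#' @param geom A `task_geometry`.
#' @rdname read_geometry
#' @export
write_geometry <- function(geom, path) {
  stopifnot(inherits(geom, "task_geometry"))
  yaml::write_yaml(
    list(
      start_center = geom$start_center,
      end_center = geom$end_center,
      circle_radius = geom$circle_radius,
      endpoint_tolerance = geom$endpoint_tolerance,
      time_limit = geom$time_limit,
      screen_width = geom$screen_width,
      screen_height = geom$screen_height,
      pixels_per_mm_x = unname(geom$pixels_per_mm["x"]),
      pixels_per_mm_y = unname(geom$pixels_per_mm["y"])
    ),
    path
  )
  invisible(path)
}
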