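# internal helpers shared across modules

PATH_KEY_COLS <- c("participant_id", "session_index", "path_id")

TRAJECTORY_COLS <- c(
  "participant_id", "session_index", "condition", "task_kind",
  "path_id", "sample_index", "t_s", "x_mm", "y_mm"
)

# composite per-path key; \x1f is the ASCII unit separator, which cannot
# occur in well-formed identifiers
og_key <- function(df) {
  paste(df$participant_id, df$session_index, df$path_id, sep = "\x1f")
}

og_key_of <- function(participant_id, session_index, path_id) {
  paste(participant_id, session_index, path_id, sep = "\x1f")
}

# stable per-path split preserving first-appearance order
split_paths <- function(df) {
  key <- og_key(df)
  split(df, factor(key, levels = unique(key)))
}

assert_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ), class = "og_format_error")
  }
  invisible(df)
}

# Euclidean length of the polyline through (x, y)
polyline_length <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

# drop consecutive duplicate positions (touchscreens emit repeats)
dedupe_points <- function(x, y) {
  if (length(x) < 2) return(list(x = x, y = y))
  keep <- c(TRUE, diff(x) != 0 | diff(y) != 0)
  list(x = x[keep], y = y[keep])
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x == as.integer(x)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
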