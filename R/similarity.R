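#' Build per-path feature vectors
#'
#' Assembles, for every resampled path, the feature vector
#' \eqn{v = [h_x, h_y, \dot h_x, \dot h_y, \ddot h_x, \ddot h_y]}:
#' the 200 arc-length-uniform x and y coordinates, followed by the first and
#' second discrete derivatives of each coordinate along the path, averaged
#' over consecutive bins of `bin_size` resampled indices (after resampling,
#' one index step is one arc-length unit). With the defaults (200 points,
#' bins of 10) each derivative component contributes 20 values, for a
#' 480-value vector per path. The first derivative is
#' \eqn{\dot h(k) = h(k) - h(k-1)}, with the first value replicated
#' (\eqn{\dot h(1) = \dot h(2)}) so each component keeps 200 values and bins
#' evenly; the second derivative is the same operator applied to
#' \eqn{\dot h}. With this padding a straight path has exactly constant
#' first-derivative features and exactly zero curvature features.
#'
#' The mirror-image features (x reflected about the vertical task axis, and
#' the correspondingly negated x-derivatives) are computed alongside, since
#' the path distance is minimized over the mirror image.
#'
#' @param resampled Output of [resample_paths()].
#' @param geometry A [task_geometry()] (supplies the mirror axis).
#' @param bin_size Derivative bin width in resampled indices; must divide
#'   the number of resampled points. Default 10.
#' @param derivative_weight Multiplier applied to the derivative blocks
#'   (default 1, i.e. raw resampled units). Exposed for sensitivity
#'   analysis of how curvature is weighted against position.
#' @return An object of class `og_features`: feature matrix `v`
#'   (paths x features), `mirror_v`, and an `info` tibble aligned with the
#'   rows.
#' @export
path_features <- function(resampled, geometry, bin_size = 10,
                          derivative_weight = 1.0) {
  stopifnot(inherits(geometry, "task_geometry"))
  assert_columns(resampled, c("participant_id", "session_index", "condition",
                              "path_id", "point_index", "x_mm", "y_mm"),
                 "resampled table")
  axis_x <- geometry_axis_x(geometry)
  res <- arrange(resampled, participant_id, session_index, path_id,
                 point_index)
  counts <- count(res, participant_id, session_index, path_id)
  n_resample <- counts$n[1]
  if (any(counts$n != n_resample)) {
    abort("all paths must have the same number of resampled points")
  }
  if (n_resample %% bin_size != 0) {
    abort(sprintf("bin_size (%d) must divide n_resample (%d)",
                  bin_size, n_resample), class = "og_config_error")
  }
  n_paths <- nrow(counts)
  X <- matrix(res$x_mm, nrow = n_paths, ncol = n_resample, byrow = TRUE)
  Y <- matrix(res$y_mm, nrow = n_paths, ncol = n_resample, byrow = TRUE)
  info <- distinct(res, participant_id, session_index, condition, path_id)
  v <- feature_block(X, Y, bin_size, derivative_weight)
  mirror_v <- feature_block(2 * axis_x - X, Y, bin_size, derivative_weight)
  structure(
    list(
      v = v,
      mirror_v = mirror_v,
      info = info,
      n_resample = n_resample,
      bin_size = bin_size,
      derivative_weight = derivative_weight,
      axis_x = axis_x
    ),
    class = "og_features"
  )
}

# layout: [hx (n), hy (n), hx_dot (n/bin), hy_dot, hx_ddot, hy_ddot]
# The discrete derivative has n - 1 natural values from n points; the first
# value is replicated so each component keeps n values and bins evenly, and
# so straight segments have exactly constant first and exactly zero second
# derivatives everywhere.
feature_block <- function(X, Y, bin_size, derivative_weight) {
  n <- ncol(X)
  pad_diff <- function(M) {
    D <- M[, -1, drop = FALSE] - M[, -n, drop = FALSE]
    cbind(D[, 1], D)
  }
  DX <- pad_diff(X); DY <- pad_diff(Y)
  DDX <- pad_diff(DX); DDY <- pad_diff(DY)
  n_bins <- n / bin_size
  B <- matrix(0, n, n_bins)
  B[cbind(seq_len(n), rep(seq_len(n_bins), each = bin_size))] <- 1 / bin_size
  w <- derivative_weight
  cbind(X, Y, (DX %*% B) * w, (DY %*% B) * w, (DDX %*% B) * w, (DDY %*% B) * w)
}

#' @export
print.og_features <- function(x, ...) {
  cat(sprintf(
    "<og_features> %d paths x %d features (%d resampled points, bins of %d)\n",
    nrow(x$v), ncol(x$v), x$n_resample, x$bin_size))
  invisible(x)
}

n_features_paths <- function(x) nrow(x$v)

#' Reflect resampled paths about the vertical task axis
#'
#' Returns the left-right mirror image of each path: x-coordinates are
#' reflected about the vertical line through the two circle centers, y is
#' unchanged. Reflection preserves arc length. Mirroring is an exact
#' involution: the pre-image coordinates are carried along, so mirroring a
#' mirrored table returns the original bit-for-bit.
#'
#' @param resampled Output of [resample_paths()] (any table with `x_mm`).
#' @param geometry A [task_geometry()] whose start/end centers share x;
#'   a non-vertical task axis is unsupported and raises an error.
#' @return The table with reflected `x_mm`.
#' @export
mirror_paths <- function(resampled, geometry) {
  axis_x <- geometry_axis_x(geometry)
  pre <- attr(resampled, "og_premirror")
  if (!is.null(pre)) {
    out <- resampled
    out$x_mm <- pre
    attr(out, "og_premirror") <- NULL
    return(out)
  }
  out <- resampled
  out$x_mm <- 2 * axis_x - resampled$x_mm
  attr(out, "og_premirror") <- resampled$x_mm
  out
}

#' Mirror-min distance between two paths
#'
#' The dissimilarity between paths i and j is the p-norm of the difference
#' of their feature vectors, minimized over the left-right mirror image of
#' one of them:
#' \eqn{d_{ij} = \min(\|v_i - v_j\|_p, \|v_i - v'_j\|_p)} where \eqn{v'_j}
#' are the mirror-image features. Identical paths and exact mirror images
#' are at distance 0. Because of the mirror minimum the triangle inequality
#' is not guaranteed.
#'
#' @param a,b `og_features` objects holding a single path each (build them
#'   with [path_features()] on one-path tables), or the same object with
#'   row indices given via `i`/`j`.
#' @param p_norm Norm order, one of 1, 2, 3 (default 2).
#' @param i,j Optional row indices when `a` (and `b`) hold several paths.
#' @return A non-negative scalar.
#' @export
path_distance <- function(a, b = a, p_norm = 2, i = 1L, j = 1L) {
  stopifnot(inherits(a, "og_features"), inherits(b, "og_features"))
  check_p_norm(p_norm)
  if (ncol(a$v) != ncol(b$v)) {
    abort("feature layouts differ between the two paths")
  }
  va <- a$v[i, ]
  min(
    pnorm_vec(va - b$v[j, ], p_norm),
    pnorm_vec(va - b$mirror_v[j, ], p_norm)
  )
}

pnorm_vec <- function(x, p) {
  if (p == 2) sqrt(sum(x * x)) else sum(abs(x)^p)^(1 / p)
}

check_p_norm <- function(p) {
  if (!is_scalar_number(p) || !p %in% c(1, 2, 3)) {
    abort("p_norm must be 1, 2 or 3")
  }
}

#' Pairwise mirror-min dissimilarity matrix
#'
#' Computes every pairwise [path_distance()] over a set of paths. The
#' matrix is symmetric with a zero diagonal; all entries are non-negative.
#'
#' @param features An `og_features` with at least two paths.
#' @param p_norm Norm order (1, 2 or 3; default 2).
#' @return A symmetric numeric matrix with the composite path keys as
#'   dimnames and attribute `p_norm`.
#' @export
distance_matrix <- function(features, p_norm = 2) {
  stopifnot(inherits(features, "og_features"))
  check_p_norm(p_norm)
  n <- n_features_paths(features)
  if (n < 2) abort("distance_matrix needs at least 2 paths")
  if (anyNA(features$v)) abort("feature matrix contains missing values")
  D <- mirror_min_dist_cpp(t(features$v), t(features$mirror_v),
                           as.numeric(p_norm))
  keys <- og_key(features$info)
  dimnames(D) <- list(keys, keys)
  attr(D, "p_norm") <- p_norm
  D
}

#' Nearest-neighbour uniqueness scores
#'
#' A path's uniqueness is its smallest mirror-min distance to any *other*
#' path in the pooled corpus, \eqn{u_i = \min_{j \ne i} d_{ij}} — pooled
#' over every participant and session present in `features`, not within
#' participant. A path with an exact duplicate or exact mirror duplicate
#' anywhere in the corpus scores 0; enlarging the corpus can only decrease
#' (never increase) an existing score. The achieved nearest neighbour is
#' recorded for audit.
#'
#' @param features An `og_features` over the whole pooled corpus (>= 2
#'   paths).
#' @param p_norm Norm order (1, 2 or 3; default 2).
#' @return A tibble with one row per path: identifiers, `ui`,
#'   `nearest_neighbour_id` (composite `participant/session/path` label),
#'   `p_norm`.
#' @export
uniqueness_scores <- function(features, p_norm = 2) {
  stopifnot(inherits(features, "og_features"))
  n <- n_features_paths(features)
  if (n < 2) abort("uniqueness needs a corpus of at least 2 paths")
  D <- distance_matrix(features, p_norm = p_norm)
  diag(D) <- Inf
  nn <- max.col(-D, ties.method = "first")
  keys_readable <- with(features$info,
                        paste(participant_id, session_index, path_id,
                              sep = "/"))
  features$info |>
    mutate(
      ui = D[cbind(seq_len(n), nn)],
      nearest_neighbour_id = keys_readable[nn],
      p_norm = p_norm
    )
}

#' Score every path of a cohort
#'
#' End-to-end per-path metrics: validity against the task geometry, drawing
#' duration, and — for valid option-generation paths — the nearest-neighbour
#' uniqueness over the cohort-wide pooled corpus. To pool several cohorts
#' (e.g. multiple studies) combine them first with [combine_cohorts()].
#'
#' @param x An `og_cohort`.
#' @param p_norm Norm order for the path distance (default 2).
#' @param smooth If `TRUE`, apply the 250 ms moving average before
#'   resampling (tremor control analysis). Validity is always judged on the
#'   raw trajectories.
#' @param smooth_window_s Smoothing window in seconds (default 0.25).
#' @param n_resample Resampled points per path (default 200).
#' @param bin_size Derivative bin width (default 10).
#' @param derivative_weight Weight of the derivative feature blocks
#'   (default 1).
#' @return A tibble with one row per path: identifiers, `valid`, `reason`,
#'   `onset_s`, `duration_s`, `ui` (`NA` for invalid or non-generation
#'   paths), `nearest_neighbour_id`, `p_norm`.
#' @export
score_paths <- function(x, p_norm = 2, smooth = FALSE,
                        smooth_window_s = 0.25, n_resample = 200,
                        bin_size = 10, derivative_weight = 1.0) {
  stopifnot(inherits(x, "og_cohort"))
  flags <- validate_paths(x)
  tr <- x$trajectories
  gen_keys <- og_key(filter(flags, valid, task_kind == "option_generation"))
  scored <- NULL
  if (length(gen_keys) >= 2) {
    sub <- tr[og_key(tr) %in% gen_keys, ]
    if (smooth) sub <- smooth_trajectories(sub, window = smooth_window_s)
    res <- resample_paths(sub, n_resample = n_resample)
    feats <- path_features(res, x$geometry, bin_size = bin_size,
                           derivative_weight = derivative_weight)
    scored <- uniqueness_scores(feats, p_norm = p_norm)
  }
  out <- flags
  if (is.null(scored)) {
    out$ui <- NA_real_
    out$nearest_neighbour_id <- NA_character_
  } else {
    out <- left_join(
      out,
      select(scored, participant_id, session_index, path_id, ui,
             nearest_neighbour_id),
      by = c("participant_id", "session_index", "path_id")
    )
  }
  out$p_norm <- p_norm
  out
}
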