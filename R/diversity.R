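#' Metric multidimensional scaling by stress majorization
#'
#' Embeds a dissimilarity matrix into `n_dims` dimensions by minimizing the
#' normalized metric stress
#' \deqn{\sigma(X) = \sum_{i<j} (\delta_{ij} - d_{ij})^2 / \sum_{i<j} d_{ij}^2,}
#' where \eqn{d} are the input dissimilarities and \eqn{\delta} the embedded
#' Euclidean distances, using iterative majorization (SMACOF / Guttman
#' transform). The first start is classical scaling (`cmdscale`); the
#' remaining `n_restarts - 1` starts are seeded random configurations, and
#' the solution with the lowest stress is kept, so results are deterministic
#' given `seed`. Stress decreases monotonically across majorization
#' iterations (the per-iteration trace is returned).
#'
#' Mirror-min dissimilarities may violate the triangle inequality; an
#' embedding is still returned, with positive stress measuring the misfit.
#' The embedding is unique only up to rotation, reflection and translation,
#' which is why downstream dispersion summaries use the isometry-invariant
#' convex-hull area.
#'
#' @param d Symmetric dissimilarity matrix (zero diagonal) or a
#'   [stats::dist] object; entries must be finite.
#' @param n_dims Embedding dimension (default 2).
#' @param seed Integer seed controlling the random restarts.
#' @param n_restarts Total number of starts including classical scaling
#'   (default 4).
#' @param max_iter Iteration cap per start (default 512).
#' @param tol Stop when the stress improvement falls below this (default
#'   1e-8).
#' @return An object of class `og_embedding`: `points` (tibble with
#'   `path_id` labels and `mds1..mdsK`), `stress`, `n_iter`, `seed`,
#'   `stress_trace`, `converged`.
#' @export
mds_embed <- function(d, n_dims = 2, seed = 1L, n_restarts = 4,
                      max_iter = 512, tol = 1e-8) {
  d <- as.matrix(d)
  if (anyNA(d) || any(!is.finite(d))) {
    abort("dissimilarity matrix contains missing or non-finite values")
  }
  n <- nrow(d)
  if (n < 2) abort("mds_embed needs at least 2 objects")
  if (max(abs(d - t(d))) > 1e-8 * max(1, max(abs(d)))) {
    abort("dissimilarity matrix must be symmetric")
  }
  d <- (d + t(d)) / 2
  diag(d) <- 0
  labels <- rownames(d) %||% as.character(seq_len(n))
  denom <- sum(d[upper.tri(d)]^2)
  if (denom == 0) {
    pts <- matrix(0, n, n_dims)
    return(new_embedding(pts, labels, 0, 0L, seed, numeric(0), TRUE))
  }
  starts <- list(classical_start(d, n_dims))
  if (n_restarts > 1) {
    extra <- withr::with_seed(seed, {
      lapply(seq_len(n_restarts - 1), function(k) {
        matrix(rnorm(n * n_dims, sd = max(d) / 2), n, n_dims)
      })
    })
    starts <- c(starts, extra)
  }
  best <- NULL
  for (X0 in starts) {
    fit <- majorize(d, X0, denom, max_iter, tol)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  new_embedding(best$X, labels, best$stress, best$n_iter, seed,
                best$trace, best$converged)
}

classical_start <- function(d, n_dims) {
  n <- nrow(d)
  X <- suppressWarnings(cmdscale(d, k = min(n_dims, n - 1)))
  if (!is.matrix(X)) X <- matrix(X, ncol = 1)
  if (ncol(X) < n_dims) {
    X <- cbind(X, matrix(0, n, n_dims - ncol(X)))
  }
  X
}

majorize <- function(d, X, denom, max_iter, tol) {
  n <- nrow(d)
  delta <- as.matrix(dist(X))
  stress <- sum((delta - d)[upper.tri(d)]^2) / denom
  trace <- stress
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    ratio <- ifelse(delta > 0, d / delta, 0)
    B <- -ratio
    diag(B) <- rowSums(ratio)
    X <- B %*% X / n
    delta <- as.matrix(dist(X))
    new_stress <- sum((delta - d)[upper.tri(d)]^2) / denom
    trace <- c(trace, new_stress)
    if (stress - new_stress < tol) {
      stress <- min(stress, new_stress)
      converged <- TRUE
      break
    }
    stress <- new_stress
  }
  list(X = X, stress = stress, n_iter = iter, trace = trace,
       converged = converged)
}

new_embedding <- function(X, labels, stress, n_iter, seed, trace, converged) {
  pts <- as_tibble(as.data.frame(X), .name_repair = "minimal")
  names(pts) <- paste0("mds", seq_len(ncol(X)))
  pts <- bind_cols(tibble(path_id = labels), pts)
  structure(
    list(points = pts, stress = stress, n_iter = n_iter, seed = seed,
         stress_trace = trace, converged = converged),
    class = "og_embedding"
  )
}

#' @export
print.og_embedding <- function(x, ...) {
  cat(sprintf("<og_embedding> %d points, stress %.3g (%d iterations%s)\n",
              nrow(x$points), x$stress, x$n_iter,
              if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' Convex-hull area of an embedding
#'
#' Area of the convex hull of the embedded points (standard hull plus
#' shoelace formula) — the exploration-area summary of how widely a
#' session's paths cover the similarity space. Fewer than three distinct
#' points, or collinear points, give area 0. The area is invariant under
#' any isometry of the embedding, so the orientation indeterminacy of
#' multidimensional scaling cannot affect it.
#'
#' @param x An `og_embedding`, a two-column matrix, or a data frame with
#'   two numeric coordinate columns.
#' @return An object of class `og_hull`: `area`, `vertices` (indices into
#'   the input points, counter-clockwise), `n_points`.
#' @export
convex_hull_area <- function(x) {
  pts <- if (inherits(x, "og_embedding")) {
    as.matrix(x$points[, c("mds1", "mds2")])
  } else if (is.matrix(x)) {
    x
  } else {
    as.matrix(as.data.frame(x)[, 1:2])
  }
  stopifnot(ncol(pts) == 2)
  distinct_pts <- unique(pts)
  area <- 0
  vertices <- integer(0)
  if (nrow(distinct_pts) >= 3) {
    hull <- rev(grDevices::chull(pts))  # counter-clockwise
    hx <- pts[hull, 1]
    hy <- pts[hull, 2]
    nxt <- c(2:length(hull), 1)
    area <- abs(sum(hx * hy[nxt] - hx[nxt] * hy)) / 2
    vertices <- hull
  }
  structure(list(area = area, vertices = vertices, n_points = nrow(pts)),
            class = "og_hull")
}

#' @export
print.og_hull <- function(x, ...) {
  cat(sprintf("<og_hull> area %.4g over %d points (%d hull vertices)\n",
              x$area, x$n_points, length(x$vertices)))
  invisible(x)
}

#' Per-session diversity: embedding stress and exploration area
#'
#' For each session, computes the mirror-min dissimilarity matrix over the
#' session's valid option-generation paths, embeds it in 2-D with
#' [mds_embed()], and summarizes dispersion as the convex-hull area of the
#' embedded points. Sessions with fewer than 3 valid paths get hull area 0
#' (logged as a warning — diversity is undefined but reportable); sessions
#' with fewer than 2 valid paths additionally get `NA` stress.
#'
#' @param x An `og_cohort`.
#' @param p_norm Norm order for the path distance (default 2).
#' @param seed Base seed; session k uses `seed + k`.
#' @param smooth,smooth_window_s,n_resample,bin_size,derivative_weight As in
#'   [score_paths()].
#' @param n_restarts Multidimensional-scaling restarts (default 4).
#' @param keep_embeddings If `TRUE`, attach the list of `og_embedding`
#'   objects as attribute `"embeddings"`.
#' @return A tibble with one row per option-generation session:
#'   `participant_id`, `session_index`, `condition`, `n_paths` (valid),
#'   `stress`, `hull_area`, `seed_used`.
#' @export
session_diversity <- function(x, p_norm = 2, seed = 1L, smooth = FALSE,
                              smooth_window_s = 0.25, n_resample = 200,
                              bin_size = 10, derivative_weight = 1.0,
                              n_restarts = 4, keep_embeddings = FALSE) {
  stopifnot(inherits(x, "og_cohort"))
  flags <- validate_paths(x)
  gen <- filter(flags, task_kind == "option_generation")
  sessions <- distinct(gen, participant_id, session_index, condition)
  tr <- x$trajectories
  embeddings <- list()
  rows <- vector("list", nrow(sessions))
  for (k in seq_len(nrow(sessions))) {
    sess <- sessions[k, ]
    sess_flags <- semi_join(gen, sess,
                            by = c("participant_id", "session_index"))
    keys <- og_key(filter(sess_flags, valid))
    n_valid <- length(keys)
    stress_k <- NA_real_
    area_k <- 0
    if (n_valid >= 2) {
      sub <- tr[og_key(tr) %in% keys, ]
      if (smooth) sub <- smooth_trajectories(sub, window = smooth_window_s)
      res <- resample_paths(sub, n_resample = n_resample)
      feats <- path_features(res, x$geometry, bin_size = bin_size,
                             derivative_weight = derivative_weight)
      D <- distance_matrix(feats, p_norm = p_norm)
      emb <- mds_embed(D, n_dims = 2, seed = seed + k,
                       n_restarts = n_restarts)
      stress_k <- emb$stress
      area_k <- convex_hull_area(emb)$area
      if (keep_embeddings) {
        embeddings[[paste(sess$participant_id, sess$session_index,
                          sep = "/")]] <- emb
      }
    }
    if (n_valid < 3) {
      warn(sprintf(
        "session %s/%s has %d valid path(s); hull area set to 0",
        sess$participant_id, sess$session_index, n_valid))
    }
    rows[[k]] <- tibble(
      participant_id = sess$participant_id,
      session_index = sess$session_index,
      condition = sess$condition,
      n_paths = n_valid,
      stress = stress_k,
      hull_area = area_k,
      seed_used = seed + k
    )
  }
  out <- bind_rows(rows)
  if (keep_embeddings) attr(out, "embeddings") <- embeddings
  out
}

#' Plot an embedding with its convex hull
#'
#' @param object An `og_embedding`.
#' @param ... Unused.
#' @return A ggplot: embedded points plus the shaded convex hull.
#' @method autoplot og_embedding
#' @export
autoplot.og_embedding <- function(object, ...) {
  pts <- object$points
  hull <- convex_hull_area(object)
  hull_pts <- pts[hull$vertices, , drop = FALSE]
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = mds1, y = mds2))
  if (nrow(hull_pts) >= 3) {
    p <- p + ggplot2::geom_polygon(data = hull_pts, fill = "steelblue",
                                   alpha = 0.15, colour = "steelblue")
  }
  p +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "dimension 1", y = "dimension 2",
      title = sprintf("Path similarity space (stress %.3g)", object$stress)
    )
}
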