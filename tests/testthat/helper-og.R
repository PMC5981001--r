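# fixtures and independent reference implementations used across tests

default_geom <- task_geometry()

# one-path trajectory table from raw vectors
make_traj <- function(x, y, t = seq_along(x) - 1, path_id = "p001",
                      participant_id = "a01", session_index = 1L,
                      condition = "none",
                      task_kind = "option_generation") {
  tibble::tibble(
    participant_id = participant_id,
    session_index = as.integer(session_index),
    condition = condition,
    task_kind = task_kind,
    path_id = path_id,
    sample_index = seq_along(x),
    t_s = as.numeric(t),
    x_mm = as.numeric(x),
    y_mm = as.numeric(y)
  )
}

# straight chord from start circle to goal circle
straight_traj <- function(geom = default_geom, n = 50, ...) {
  make_traj(
    x = seq(geom$start_center[1], geom$end_center[1], length.out = n),
    y = seq(geom$start_center[2], geom$end_center[2], length.out = n),
    ...
  )
}

# bundle of valid wiggly paths (one session), via the simulator
random_session <- function(n_paths = 10, sigma = 20, seed = 1,
                           geom = default_geom, participant_id = "a01") {
  agent <- agent_params(dispersion = sigma, speed = 150,
                        uniqueness_cost = 0)
  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(n_paths), function(k) {
      p <- simulate_path(agent, geom, path_index = k)
      make_traj(p$x_mm, p$y_mm, t = p$t_s, path_id = p$path_id[1],
                participant_id = participant_id)
    }))
  })
}

# ---- independent oracles (plain loops, no package internals) ----

naive_pnorm <- function(a, b, p) {
  s <- 0
  for (k in seq_along(a)) s <- s + abs(a[k] - b[k])^p
  s^(1 / p)
}

# feature vector by explicit loops: [x, y, binned dx, dy, ddx, ddy]
naive_feature_vector <- function(x, y, bin_size = 10, w = 1) {
  n <- length(x)
  d1 <- function(v) {
    out <- numeric(n)
    for (k in 2:n) out[k] <- v[k] - v[k - 1]
    out[1] <- out[2]  # replicate padding, as documented
    out
  }
  binmean <- function(v) {
    nb <- n / bin_size
    out <- numeric(nb)
    for (b in seq_len(nb)) {
      idx <- ((b - 1) * bin_size + 1):(b * bin_size)
      out[b] <- mean(v[idx])
    }
    out
  }
  dx <- d1(x); dy <- d1(y)
  ddx <- d1(dx); ddy <- d1(dy)
  c(x, y, w * binmean(dx), w * binmean(dy), w * binmean(ddx), w * binmean(ddy))
}

# full mirror-min matrix from feature and mirror-feature matrices
naive_mirror_min_matrix <- function(V, M, p) {
  n <- nrow(V)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      D[i, j] <- min(naive_pnorm(V[i, ], V[j, ], p),
                     naive_pnorm(V[i, ], M[j, ], p))
    }
  }
  D
}

naive_uniqueness <- function(V, M, p) {
  D <- naive_mirror_min_matrix(V, M, p)
  diag(D) <- Inf
  apply(D, 1, min)
}

# convex hull area via gift wrapping (independent of grDevices::chull)
jarvis_hull_area <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 3) return(0)
  start <- which.min(pts[, 1])
  hull <- start
  repeat {
    p <- hull[length(hull)]
    q <- if (p == n) 1 else p + 1
    for (r in seq_len(n)) {
      cross <- (pts[q, 1] - pts[p, 1]) * (pts[r, 2] - pts[p, 2]) -
        (pts[q, 2] - pts[p, 2]) * (pts[r, 1] - pts[p, 1])
      if (cross < 0) q <- r
    }
    if (q == start) break
    hull <- c(hull, q)
    if (length(hull) > n) break
  }
  hx <- pts[hull, 1]; hy <- pts[hull, 2]
  nxt <- c(seq_along(hull)[-1], 1)
  abs(sum(hx * hy[nxt] - hx[nxt] * hy)) / 2
}
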