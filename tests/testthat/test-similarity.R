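features_of <- function(traj, geom = default_geom, ...) {
  path_features(resample_paths(traj), geom, ...)
}

test_that("the feature vector has the documented 480-value layout", {
  tr <- random_session(n_paths = 3, sigma = 20, seed = 1)
  res <- resample_paths(tr)
  f <- path_features(res, default_geom)
  expect_equal(ncol(f$v), 480)
  expect_equal(ncol(f$mirror_v), 480)
  # first 400 values are the resampled coordinates, x block then y block
  one <- dplyr::filter(res, path_id == "p001")
  expect_equal(f$v[1, 1:200], one$x_mm)
  expect_equal(f$v[1, 201:400], one$y_mm)
  # 20 bin-averaged values per derivative component
  expect_equal(ncol(f$v) - 400, 4 * 20)
})

test_that("a vertical straight line has zero x-derivative and zero curvature features", {
  straight <- make_traj(x = rep(254.5, 2), y = c(41, 245))
  f <- features_of(straight)
  expect_equal(unname(f$v[1, 401:420]), rep(0, 20))     # dx bins
  expect_equal(unname(f$v[1, 441:480]), rep(0, 40))     # ddx and ddy bins
  # constant y step in every bin
  expect_equal(unname(f$v[1, 421:440]), rep(204 / 199, 20), tolerance = 1e-9)
})

test_that("bin averages match a brute-force loop oracle", {
  tr <- random_session(n_paths = 4, sigma = 30, seed = 2)
  res <- resample_paths(tr)
  f <- path_features(res, default_geom, derivative_weight = 1.5)
  for (pid in unique(res$path_id)) {
    one <- dplyr::filter(res, path_id == pid)
    want <- naive_feature_vector(one$x_mm, one$y_mm, bin_size = 10, w = 1.5)
    got <- f$v[which(f$info$path_id == pid), ]
    expect_equal(unname(got), want, tolerance = 1e-12)
  }
})

test_that("bin size must divide the resampling grid", {
  tr <- random_session(n_paths = 2, seed = 3)
  expect_error(path_features(resample_paths(tr), default_geom, bin_size = 7),
               class = "og_config_error")
})

test_that("mirroring reflects about the task axis and is an exact involution", {
  tr <- random_session(n_paths = 2, sigma = 25, seed = 4)
  res <- resample_paths(tr)
  mir <- mirror_paths(res, default_geom)
  expect_equal(mir$x_mm, 2 * 254.5 - res$x_mm)
  expect_identical(mirror_paths(mir, default_geom)$x_mm, res$x_mm)
  expect_equal(mir$y_mm, res$y_mm)

  on_axis <- resample_paths(make_traj(x = rep(254.5, 2), y = c(41, 245)))
  expect_equal(mirror_paths(on_axis, default_geom)$x_mm, on_axis$x_mm)

  # reflection preserves arc length (a C bulging left bulges right), and
  # flips which side of the axis the path bulges to
  one <- dplyr::filter(res, path_id == "p001")
  one_mir <- dplyr::filter(mir, path_id == "p001")
  len_of <- function(df) sum(sqrt(diff(df$x_mm)^2 + diff(df$y_mm)^2))
  expect_equal(len_of(one_mir), len_of(one), tolerance = 1e-12)
  expect_equal(mean(one_mir$x_mm - 254.5), -mean(one$x_mm - 254.5),
               tolerance = 1e-12)

  skewed <- task_geometry(start_center = c(100, 41), end_center = c(254.5, 245))
  expect_error(mirror_paths(res, skewed), class = "og_geometry_error")
})

test_that("mirror features of a path equal the features of its mirrored path", {
  tr <- random_session(n_paths = 2, sigma = 25, seed = 5)
  res <- resample_paths(tr)
  f <- path_features(res, default_geom)
  f_mirrored <- path_features(mirror_paths(res, default_geom), default_geom)
  expect_identical(f$mirror_v, f_mirrored$v)
  # double reflection in floating point is exact only up to the last ulp;
  # exact involution is provided by mirror_paths(), asserted elsewhere
  expect_equal(f_mirrored$mirror_v, f$v, tolerance = 1e-12)
})

test_that("path distance is zero for self and exact mirror duplicates, and symmetric", {
  tr <- random_session(n_paths = 2, sigma = 25, seed = 6)
  res <- resample_paths(tr)
  f <- path_features(res, default_geom)
  expect_equal(path_distance(f, f, i = 1, j = 1), 0)

  mir <- mirror_paths(res, default_geom)
  mir$path_id <- paste0(mir$path_id, "m")
  fm <- path_features(dplyr::bind_rows(res, mir), default_geom)
  D <- distance_matrix(fm)
  for (pid in c("p001", "p002")) {
    i <- which(fm$info$path_id == pid)
    j <- which(fm$info$path_id == paste0(pid, "m"))
    expect_identical(D[i, j], 0)  # exact mirror duplicate
  }

  for (p in c(1, 2, 3)) {
    d_ab <- path_distance(f, f, p_norm = p, i = 1, j = 2)
    d_ba <- path_distance(f, f, p_norm = p, i = 2, j = 1)
    expect_equal(d_ab, d_ba, tolerance = 1e-12)
    va <- f$v[1, ]; vb <- f$v[2, ]; mb <- f$mirror_v[2, ]
    expect_equal(d_ab, min(naive_pnorm(va, vb, p), naive_pnorm(va, mb, p)),
                 tolerance = 1e-12)
  }
  expect_error(path_distance(f, f, p_norm = 4), "p_norm")
})

test_that("the distance matrix equals the naive double loop and respects permutations", {
  tr <- random_session(n_paths = 8, sigma = 25, seed = 7)
  res <- resample_paths(tr)
  f <- path_features(res, default_geom)
  for (p in c(1, 2, 3)) {
    D <- distance_matrix(f, p_norm = p)
    expect_true(isSymmetric(unclass(D), check.attributes = FALSE))
    expect_equal(unname(diag(D)), rep(0, 8))
    want <- naive_mirror_min_matrix(f$v, f$mirror_v, p)
    expect_equal(unname(D), want, tolerance = 1e-12, ignore_attr = TRUE)
  }
  # shuffling the input rows leaves the keyed matrix unchanged: entries are
  # tied to path identities, not input positions
  withr::with_seed(1, {
    res_shuffled <- res[sample.int(nrow(res)), ]
  })
  D1 <- distance_matrix(f)
  D2 <- distance_matrix(path_features(res_shuffled, default_geom))
  expect_identical(dimnames(D2), dimnames(D1))
  expect_equal(unname(D2), unname(D1), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("identical paths give a zero distance matrix and zero uniqueness", {
  one <- random_session(n_paths = 1, sigma = 20, seed = 8)
  twin <- dplyr::mutate(one, path_id = "p002")
  f <- path_features(resample_paths(dplyr::bind_rows(one, twin)),
                     default_geom)
  expect_equal(unname(distance_matrix(f)), matrix(0, 2, 2), ignore_attr = TRUE)
  u <- uniqueness_scores(f)
  expect_equal(u$ui, c(0, 0))
})

test_that("uniqueness matches brute force and never rises when the corpus grows", {
  tr <- random_session(n_paths = 12, sigma = 25, seed = 9)
  res <- resample_paths(tr)
  f <- path_features(res, default_geom)
  u <- uniqueness_scores(f)
  expect_equal(u$ui, unname(naive_uniqueness(f$v, f$mirror_v, 2)),
               tolerance = 1e-12)

  # append an exact duplicate of the first path
  dup <- dplyr::mutate(dplyr::filter(tr, path_id == "p001"),
                       path_id = "p_dup")
  f_big <- path_features(resample_paths(dplyr::bind_rows(tr, dup)),
                         default_geom)
  u_big <- uniqueness_scores(f_big)
  expect_equal(u_big$ui[u_big$path_id == "p001"], 0)
  expect_true(all(u_big$ui[1:12] <= u$ui + 1e-12))
})

test_that("distances and uniqueness scale exactly with the coordinates", {
  tr <- random_session(n_paths = 6, sigma = 25, seed = 10)
  res <- resample_paths(tr)
  f1 <- path_features(res, default_geom)
  doubled <- dplyr::mutate(tr, x_mm = 2 * x_mm, y_mm = 2 * y_mm)
  geom2 <- task_geometry(start_center = 2 * default_geom$start_center,
                         end_center = 2 * default_geom$end_center,
                         screen_width = 1018, screen_height = 572,
                         endpoint_tolerance = 42, circle_radius = 26)
  f2 <- path_features(resample_paths(doubled), geom2)
  for (p in c(1, 2, 3)) {
    expect_equal(unname(distance_matrix(f2, p)),
                 2 * unname(distance_matrix(f1, p)), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("replacing a corpus path by its mirror image leaves all distances unchanged", {
  tr <- random_session(n_paths = 6, sigma = 25, seed = 11)
  res <- resample_paths(tr)
  D1 <- distance_matrix(path_features(res, default_geom))
  flip <- dplyr::mutate(res,
    x_mm = ifelse(path_id == "p003", 2 * 254.5 - x_mm, x_mm))
  D2 <- distance_matrix(path_features(flip, default_geom))
  expect_equal(unname(D1), unname(D2), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("score_paths joins validity, duration and pooled uniqueness", {
  ch <- simulate_cohort(generator_config(n_agents = 3, seed = 12))
  m <- score_paths(ch)
  expect_true(all(m$valid))
  expect_true(all(m$ui >= 0))
  expect_true(all(m$duration_s > 0))
  expect_equal(nrow(m),
               length(unique(paste(ch$trajectories$participant_id,
                                   ch$trajectories$session_index,
                                   ch$trajectories$path_id))))
})
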