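#' Run the full analysis pipeline
#'
#' Orchestrates simulate/read -> validate -> score -> embed -> analyze ->
#' report from a single configuration, writing per-path metrics, per-session
#' diversity, session summaries, an analysis table and a JSON manifest to
#' the output directory. One master seed determines every stochastic choice
#' (cohort generation and the multidimensional-scaling restarts), so a rerun
#' of the same configuration reproduces every numeric output exactly.
#'
#' Configuration keys (YAML file or list; function arguments override the
#' file, which overrides the defaults): `seed`, `p_norm` (1/2/3), `smooth`,
#' `smooth_window_s`, `n_resample`, `bin_size`, `mds_restarts`, `out_dir`,
#' and either `simulate:` (arguments of [generator_config()] plus `design`)
#' or `input:` with `trajectories` (one path or a list to pool), optional
#' `geometry` and `covariates` files.
#'
#' @param config Path to a YAML configuration file, or an equivalent list.
#' @param out_dir Output directory (overrides the config).
#' @param seed Master seed (overrides the config).
#' @param report Write the text report and figures (default `TRUE`).
#' @return The run manifest (list, class `og_manifest`), invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL,
                         report = NULL) {
  cfg_input <- if (is.character(config)) yaml::read_yaml(config) else config
  defaults <- list(
    seed = 1L, p_norm = 2, smooth = FALSE, smooth_window_s = 0.25,
    n_resample = 200, bin_size = 10, derivative_weight = 1,
    mds_restarts = 4, out_dir = "og_output", report = TRUE,
    simulate = NULL, input = NULL
  )
  cfg <- modifyList(defaults, cfg_input)
  if (!is.null(seed)) cfg$seed <- seed
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (!is.null(report)) cfg$report <- report
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  input_hashes <- character()
  if (!is.null(cfg$input)) {
    files <- cfg$input$trajectories
    cohorts <- lapply(files, function(f) {
      read_cohort(f, geometry = cfg$input$geometry,
                  covariates = cfg$input$covariates)
    })
    ch <- combine_cohorts(cohorts)
    input_hashes <- vapply(unlist(files), function(f) {
      unname(tools::md5sum(f))
    }, "")
  } else {
    sim <- cfg$simulate %||% list()
    design <- sim$design %||% "single_session"
    sim$design <- NULL
    sim$seed <- cfg$seed
    gc_args <- sim[names(sim) %in% names(formals(generator_config))]
    ch <- simulate_cohort(do.call(generator_config, gc_args),
                          design = design)
  }

  metrics <- score_paths(ch, p_norm = cfg$p_norm, smooth = cfg$smooth,
                         smooth_window_s = cfg$smooth_window_s,
                         n_resample = cfg$n_resample,
                         bin_size = cfg$bin_size,
                         derivative_weight = cfg$derivative_weight)
  divers <- suppressWarnings(
    session_diversity(ch, p_norm = cfg$p_norm, seed = cfg$seed,
                      smooth = cfg$smooth,
                      smooth_window_s = cfg$smooth_window_s,
                      n_resample = cfg$n_resample, bin_size = cfg$bin_size,
                      derivative_weight = cfg$derivative_weight,
                      n_restarts = cfg$mds_restarts,
                      keep_embeddings = TRUE)
  )
  summaries <- suppressWarnings(summarize_sessions(ch, metrics, divers))
  analyses <- pipeline_analyses(summaries, ch, metrics)

  paths <- c(
    path_metrics = file.path(cfg$out_dir, "path_metrics.csv"),
    diversity = file.path(cfg$out_dir, "diversity.csv"),
    session_summaries = file.path(cfg$out_dir, "session_summaries.csv"),
    analyses = file.path(cfg$out_dir, "analyses.csv")
  )
  readr::write_csv(metrics, paths["path_metrics"], progress = FALSE)
  readr::write_csv(as_tibble(divers), paths["diversity"], progress = FALSE)
  readr::write_csv(summaries, paths["session_summaries"], progress = FALSE)
  readr::write_csv(analyses, paths["analyses"], progress = FALSE)

  if (isTRUE(cfg$report)) {
    embeddings <- attr(divers, "embeddings")
    report_files <- make_report(summaries, analyses, cfg$out_dir,
                                embeddings = embeddings)
    paths <- c(paths, report_files)
  }

  manifest <- structure(
    list(
      config = cfg[setdiff(names(cfg), c("input"))],
      seed = cfg$seed,
      parameters = list(n_resample = cfg$n_resample, p_norm = cfg$p_norm,
                        bin_size = cfg$bin_size,
                        endpoint_tolerance_mm = ch$geometry$endpoint_tolerance,
                        smooth = cfg$smooth,
                        smooth_window_s = cfg$smooth_window_s),
      input_hashes = as.list(input_hashes),
      package_version = as.character(utils::packageVersion("optiongen")),
      outputs = as.list(paths)
    ),
    class = "og_manifest"
  )
  jsonlite::write_json(unclass(manifest),
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# the standard battery of analyses a run reports, as far as the design allows
pipeline_analyses <- function(summaries, ch, metrics) {
  out <- list()
  gen <- filter(summaries, task_kind == "option_generation")
  ok_tradeoff <- nrow(gen) >= 3 &&
    sum(!is.na(gen$mean_uniqueness)) >= 3 &&
    sd(gen$fluency) > 0
  if (ok_tradeoff) {
    out$tradeoff <- correlate(gen, fluency, mean_uniqueness) |>
      mutate(analysis = "fluency vs mean uniqueness", .before = 1)
    if ("motivation" %in% names(gen) && sd(gen$motivation) > 0) {
      out$mot_flu <- correlate(gen, motivation, fluency) |>
        mutate(analysis = "motivation vs fluency", .before = 1)
      out$mot_uni <- correlate(gen, motivation, mean_uniqueness) |>
        mutate(analysis = "motivation vs mean uniqueness", .before = 1)
    }
  }
  conds <- setdiff(unique(gen$condition), "none")
  if (length(conds) == 2) {
    for (m in c("fluency", "mean_uniqueness", "hull_area")) {
      if (!m %in% names(gen)) next
      res <- tryCatch(
        paired_compare(gen, !!rlang::sym(m), conditions = sort(conds)) |>
          mutate(analysis = paste("paired", m), .before = 1),
        error = function(e) NULL
      )
      out[[paste0("paired_", m)]] <- res
    }
    fit <- tryCatch({
      tab <- path_level_table(ch, metrics)
      suppressWarnings(tradeoff_mixed_model(tab))
    }, error = function(e) NULL)
    if (!is.null(fit)) {
      out$mixed <- tidy(fit) |>
        mutate(analysis = "mixed model: uniqueness ~ duration + condition",
               .before = 1)
    }
  }
  bind_rows(out)
}

#' Write the human-readable report
#'
#' Produces `report.txt` (one block per analysis plus cohort-level
#' descriptives) and, where the inputs allow, `fig_tradeoff.png`
#' (mean uniqueness against fluency across sessions) and
#' `fig_embedding.png` (one session's similarity-space point cloud with its
#' convex hull). Regeneration from the same inputs is deterministic. An
#' empty analysis table yields a header-only report.
#'
#' @param summaries Session summaries.
#' @param analyses Analysis table (possibly empty).
#' @param out_dir Output directory.
#' @param embeddings Optional named list of `og_embedding` objects; the
#'   first is plotted.
#' @return Named character vector of the files written, invisibly.
#' @export
make_report <- function(summaries, analyses, out_dir,
                        embeddings = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(report = file.path(out_dir, "report.txt"))
  lines <- c("option-generation analysis report",
             strrep("=", 34), "")
  gen <- filter(summaries, task_kind == "option_generation")
  if (nrow(gen) > 0) {
    lines <- c(lines, sprintf(
      "sessions: %d | fluency %.1f +/- %.1f | mean uniqueness %.2f +/- %.2f",
      nrow(gen), mean(gen$fluency), sd(gen$fluency),
      mean(gen$mean_uniqueness, na.rm = TRUE),
      sd(gen$mean_uniqueness, na.rm = TRUE)), "")
  }
  if (nrow(analyses) > 0) {
    for (i in seq_len(nrow(analyses))) {
      row <- analyses[i, ]
      lines <- c(lines, sprintf(
        "%-45s est %8.4f  stat %8.3f  p %.4g",
        substr(row$analysis %||% row$method, 1, 45),
        row$estimate, row$statistic %||% NA_real_,
        row$p.value %||% NA_real_))
    }
  }
  writeLines(lines, files["report"])
  if (nrow(gen) >= 3 && sum(!is.na(gen$mean_uniqueness)) >= 3) {
    f <- file.path(out_dir, "fig_tradeoff.png")
    ggplot2::ggsave(f, plot_tradeoff(gen), width = 5, height = 4, dpi = 150)
    files <- c(files, fig_tradeoff = f)
  }
  if (!is.null(embeddings) && length(embeddings) > 0) {
    f <- file.path(out_dir, "fig_embedding.png")
    ggplot2::ggsave(f, autoplot(embeddings[[1]]), width = 5, height = 4,
                    dpi = 150)
    files <- c(files, fig_embedding = f)
  }
  invisible(files)
}

#' Scatterplot of the uniqueness-fluency trade-off
#'
#' Each point is one session: the number of valid paths produced against
#' their mean uniqueness, with a least-squares trend line.
#'
#' @param summaries Session summaries (needs `fluency` and
#'   `mean_uniqueness`).
#' @return A ggplot.
#' @export
plot_tradeoff <- function(summaries) {
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = fluency, y = mean_uniqueness)) +
    ggplot2::geom_point(ggplot2::aes(colour = condition), alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey30", linewidth = 0.5) +
    ggplot2::labs(x = "fluency (valid paths per session)",
                  y = "mean uniqueness (mm)",
                  colour = "condition")
}
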