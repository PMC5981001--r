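#' Session-level summaries
#'
#' Aggregates per-path metrics and per-session diversity into one row per
#' session: `fluency` (number of valid paths produced within the budget),
#' `mean_uniqueness` (arithmetic mean of the valid paths' uniqueness
#' scores; `NA` and flagged when a session has no valid path),
#' `mean_path_duration`, `hull_area`/`stress` when a diversity table is
#' supplied, and the session covariates pivoted to columns.
#'
#' @param x An `og_cohort`.
#' @param path_metrics Output of [score_paths()] on `x`.
#' @param diversity Optional output of [session_diversity()] on `x`.
#' @return A tibble with one row per session.
#' @export
summarize_sessions <- function(x, path_metrics, diversity = NULL) {
  stopifnot(inherits(x, "og_cohort"))
  sessions <- distinct(x$trajectories, participant_id, session_index,
                       condition, task_kind)
  have <- distinct(path_metrics, participant_id, session_index)
  missing <- anti_join(distinct(sessions, participant_id, session_index),
                       have, by = c("participant_id", "session_index"))
  if (nrow(missing) > 0) {
    abort(sprintf(
      "path metrics missing for session(s): %s",
      paste(sprintf("%s/%s", missing$participant_id, missing$session_index),
            collapse = ", ")
    ))
  }
  summ <- path_metrics |>
    group_by(participant_id, session_index, condition, task_kind) |>
    summarise(
      n_paths = n(),
      fluency = sum(valid),
      mean_uniqueness = if (any(valid & !is.na(ui))) {
        mean(ui[valid], na.rm = TRUE)
      } else {
        NA_real_
      },
      mean_path_duration = if (any(valid)) mean(duration_s[valid]) else NA_real_,
      .groups = "drop"
    )
  if (any(summ$fluency == 0)) {
    warn(sprintf("%d session(s) have no valid paths; mean uniqueness undefined",
                 sum(summ$fluency == 0)))
  }
  if (!is.null(diversity)) {
    summ <- left_join(
      summ,
      select(diversity, participant_id, session_index, stress, hull_area),
      by = c("participant_id", "session_index")
    )
  }
  if (nrow(x$covariates) > 0) {
    wide <- tidyr::pivot_wider(x$covariates, names_from = covariate_name,
                               values_from = value)
    summ <- left_join(summ, wide,
                      by = c("participant_id", "session_index"))
  }
  summ
}

#' Trial-level table for the duration-uniqueness analyses
#'
#' One row per valid option-generation path with its drawing duration,
#' uniqueness score, condition and (when available) the participant's
#' apathy covariate — the input to [tradeoff_mixed_model()].
#'
#' @param x An `og_cohort`.
#' @param path_metrics Output of [score_paths()].
#' @return A tibble with columns `participant_id`, `session_index`,
#'   `condition`, `path_id`, `duration_s`, `uniqueness`, plus covariates.
#' @export
path_level_table <- function(x, path_metrics) {
  stopifnot(inherits(x, "og_cohort"))
  tab <- path_metrics |>
    filter(valid, task_kind == "option_generation", !is.na(ui),
           duration_s > 0) |>
    select(participant_id, session_index, condition, path_id, duration_s,
           uniqueness = ui)
  if (nrow(x$covariates) > 0) {
    wide <- tidyr::pivot_wider(x$covariates, names_from = covariate_name,
                               values_from = value)
    tab <- left_join(tab, wide, by = c("participant_id", "session_index"))
  }
  tab
}

#' Correlation between two columns
#'
#' Thin broom-style wrapper around [stats::cor.test()]: Pearson or Spearman
#' correlation with a two-sided p-value, after pairwise deletion of missing
#' values.
#'
#' @param data A data frame.
#' @param x,y Columns (tidy evaluation).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A one-row tibble: `method`, `estimate`, `statistic`, `df`,
#'   `p.value`, `n`.
#' @export
correlate <- function(data, x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  xv <- pull(data, {{ x }})
  yv <- pull(data, {{ y }})
  keep <- complete.cases(xv, yv)
  xv <- xv[keep]; yv <- yv[keep]
  n <- length(xv)
  if (n < 3) abort("correlate needs at least 3 complete pairs")
  if (sd(xv) == 0 || sd(yv) == 0) {
    abort("correlate: a variable has zero variance")
  }
  ct <- suppressWarnings(cor.test(xv, yv, method = method, exact = FALSE))
  tibble(
    method = method,
    estimate = unname(ct$estimate),
    statistic = unname(ct$statistic),
    df = if (method == "pearson") unname(ct$parameter) else NA_real_,
    p.value = ct$p.value,
    n = n
  )
}

#' Partial correlation controlling for covariates
#'
#' Correlation between the residuals of `x` and `y` after linear regression
#' of each on the control columns (used, e.g., to show that the
#' fluency-motivation association survives regressing out baseline drawing
#' speed). With an empty control set this reduces exactly to
#' [correlate()]. Spearman partials rank-transform all variables first.
#'
#' @param data A data frame.
#' @param x,y Columns (tidy evaluation).
#' @param controls Control columns (tidyselect, e.g.
#'   `c(draw_time, age)`).
#' @param method `"pearson"` or `"spearman"`.
#' @return A one-row tibble: `method`, `estimate`, `statistic` (t), `df`,
#'   `p.value`, `n`, `n_controls`.
#' @export
partial_correlate <- function(data, x, y, controls,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  xv <- pull(data, {{ x }})
  yv <- pull(data, {{ y }})
  cm <- as.matrix(select(as_tibble(data), {{ controls }}))
  if (ncol(cm) == 0) return(correlate(data, {{ x }}, {{ y }}, method = method))
  keep <- complete.cases(xv, yv, cm)
  xv <- xv[keep]; yv <- yv[keep]
  cm <- cm[keep, , drop = FALSE]
  n <- length(xv)
  k <- ncol(cm)
  if (n < k + 3) abort("not enough complete cases for the partial correlation")
  if (method == "spearman") {
    xv <- rank(xv); yv <- rank(yv); cm <- apply(cm, 2, rank)
  }
  Xd <- cbind(1, cm)
  if (qr(Xd)$rank < ncol(Xd)) {
    abort("control variables are collinear")
  }
  rx <- lm.fit(Xd, xv)$residuals
  ry <- lm.fit(Xd, yv)$residuals
  df0 <- n - 2 - k
  if (sd(rx) < 1e-12 * max(1, sd(xv)) || sd(ry) < 1e-12 * max(1, sd(yv))) {
    # a variable fully explained by the controls: nothing left to correlate
    return(tibble(method = paste("partial", method), estimate = 0,
                  statistic = 0, df = df0, p.value = 1, n = n,
                  n_controls = k))
  }
  r <- cor(rx, ry)
  df <- n - 2 - k
  tstat <- r * sqrt(df / (1 - r^2))
  tibble(
    method = paste("partial", method),
    estimate = r,
    statistic = tstat,
    df = df,
    p.value = 2 * pt(-abs(tstat), df),
    n = n,
    n_controls = k
  )
}

#' Compare two dependent overlapping correlations
#'
#' Tests whether the correlation of `a` with `b` differs from the
#' correlation of `a` with `c`, measured on the same `n` subjects (the two
#' correlations share variable `a`, e.g. motivation correlated with fluency
#' versus with uniqueness). The default is the Fisher-transform z test for
#' dependent overlapping correlations of Meng, Rosenthal & Rubin (1992),
#' which accounts for the correlation `r_bc` between the two non-shared
#' variables; `dependent = FALSE` gives the naive independent-samples
#' Fisher z for sensitivity.
#'
#' @param r_ab,r_ac The two correlations sharing variable `a`.
#' @param r_bc Correlation between the non-shared variables.
#' @param n Sample size (> 3).
#' @param dependent Use the dependent-overlapping formulation (default).
#' @return A one-row tibble: `method`, `estimate` (`r_ab - r_ac`),
#'   `statistic` (z), `p.value`, `n`.
#' @export
compare_correlations <- function(r_ab, r_ac, r_bc, n, dependent = TRUE) {
  for (r in c(r_ab, r_ac, r_bc)) {
    if (!is_scalar_number(r) || abs(r) >= 1) {
      abort("correlations must lie strictly within (-1, 1)")
    }
  }
  if (!is_count(n) || n <= 3) abort("n must be an integer > 3")
  dz <- atanh(r_ab) - atanh(r_ac)
  if (dependent) {
    rbar2 <- (r_ab^2 + r_ac^2) / 2
    f <- min((1 - r_bc) / (2 * (1 - rbar2)), 1)
    h <- (1 - f * rbar2) / (1 - rbar2)
    z <- dz * sqrt((n - 3) / (2 * (1 - r_bc) * h))
    method <- "dependent overlapping correlations (Meng-Rosenthal-Rubin z)"
  } else {
    z <- dz / sqrt(2 / (n - 3))
    method <- "independent Fisher z (naive)"
  }
  tibble(
    method = method,
    estimate = r_ab - r_ac,
    statistic = z,
    p.value = 2 * pnorm(-abs(z)),
    n = n
  )
}

#' Trial-level mixed model of uniqueness on path duration
#'
#' Fits `uniqueness ~ duration_s + condition (+ apathy + condition:apathy)
#' (+ duration_s:condition) + (1 | participant_id)` with
#' [lmerTest::lmer()]. Because fluency and uniqueness trade off, the raw
#' condition contrast mixes "paths were faster" with "paths were more
#' unusual"; conditioning on each path's duration isolates the condition
#' effect on uniqueness at fixed fluency — the `condition` fixed effect is
#' exposed directly as `$condition_effect`. Random structure is a
#' participant-level random intercept (the smallest structure supporting
#' the within-subject design).
#'
#' @param table Output of [path_level_table()] (needs >= 2 conditions per
#'   participant; participants observed under a single condition are
#'   dropped with a warning).
#' @param condition_ref Reference condition level (default: first sorted
#'   level; pass e.g. `"OFF"` to read the contrast as the ON effect).
#' @param use_apathy Include the apathy main effect and condition x apathy
#'   interaction when an `apathy` column is present (default `TRUE`).
#' @param duration_condition Also include the duration x condition
#'   interaction (default `FALSE`).
#' @return An object of class `og_tradeoff_fit`; see [tidy.og_tradeoff_fit()].
#' @export
tradeoff_mixed_model <- function(table, condition_ref = NULL,
                                 use_apathy = TRUE,
                                 duration_condition = FALSE) {
  assert_columns(table, c("participant_id", "condition", "duration_s",
                          "uniqueness"), "path-level table")
  tab <- as_tibble(table)
  n_cond <- tab |>
    group_by(participant_id) |>
    summarise(k = n_distinct(condition), .groups = "drop")
  drop_ids <- n_cond$participant_id[n_cond$k < 2]
  if (length(drop_ids) > 0) {
    warn(sprintf("dropping %d participant(s) observed under a single condition: %s",
                 length(drop_ids), paste(drop_ids, collapse = ", ")))
    tab <- filter(tab, !participant_id %in% drop_ids)
  }
  if (n_distinct(tab$condition) < 2) {
    abort("mixed model needs at least 2 conditions")
  }
  if (n_distinct(tab$participant_id) < 10) {
    warn("fewer than 10 participants; mixed-model inference may be fragile")
  }
  levs <- sort(unique(tab$condition))
  ref <- condition_ref %||% levs[1]
  tab$condition <- stats::relevel(factor(tab$condition, levels = levs), ref)
  rhs <- "duration_s + condition"
  has_apathy <- use_apathy && "apathy" %in% names(tab) &&
    sd(tab$apathy, na.rm = TRUE) > 0
  if (has_apathy) rhs <- paste(rhs, "+ apathy + condition:apathy")
  if (duration_condition) rhs <- paste(rhs, "+ duration_s:condition")
  fml <- stats::as.formula(
    paste("uniqueness ~", rhs, "+ (1 | participant_id)"))
  model <- lmerTest::lmer(fml, data = tab)
  if (lme4::isSingular(model)) {
    warn("singular mixed-model fit; random-intercept-only structure retained")
  }
  coefs <- as.data.frame(coef(summary(model)))
  tidy_tab <- tibble(
    term = rownames(coefs),
    estimate = coefs[["Estimate"]],
    std.error = coefs[["Std. Error"]],
    df = coefs[["df"]],
    statistic = coefs[["t value"]],
    p.value = coefs[["Pr(>|t|)"]]
  )
  cond_terms <- grepl("^condition", tidy_tab$term) &
    !grepl(":", tidy_tab$term)
  structure(
    list(
      model = model,
      formula = fml,
      data = tab,
      tidy = tidy_tab,
      condition_effect = tidy_tab[cond_terms, ],
      condition_ref = ref
    ),
    class = "og_tradeoff_fit"
  )
}

#' @export
print.og_tradeoff_fit <- function(x, ...) {
  cat("<og_tradeoff_fit>", deparse(x$formula), "\n")
  print(x$tidy)
  invisible(x)
}

#' Tidy a trial-level mixed-model fit
#'
#' @param x An `og_tradeoff_fit`.
#' @param ... Unused.
#' @return Fixed-effect estimates with Satterthwaite df: one row per term
#'   with `estimate`, `std.error`, `df`, `statistic`, `p.value`.
#' @method tidy og_tradeoff_fit
#' @export
tidy.og_tradeoff_fit <- function(x, ...) x$tidy

#' @rdname tidy.og_tradeoff_fit
#' @return `glance()` returns a one-row model summary.
#' @method glance og_tradeoff_fit
#' @export
glance.og_tradeoff_fit <- function(x, ...) {
  m <- x$model
  tibble(
    nobs = stats::nobs(m),
    n_participants = length(unique(x$data$participant_id)),
    sigma = stats::sigma(m),
    logLik = as.numeric(stats::logLik(m)),
    AIC = stats::AIC(m),
    singular = lme4::isSingular(m)
  )
}

#' Paired comparison of a session measure between two conditions
#'
#' Two-sided paired t test of `measure` between the two conditions of a
#' within-subject design, with the option (default) of log-transforming
#' measures that fail a Shapiro-Wilk normality pre-check at alpha = 0.05
#' (only applied when all values are positive; the decision is recorded in
#' the output). Zero-variance differences are reported with the exact mean
#' difference and flagged instead of producing an infinite t.
#'
#' @param summaries Session summaries ([summarize_sessions()]).
#' @param measure Column to compare (tidy evaluation), e.g. `fluency`.
#' @param conditions Character vector of the two condition levels; the
#'   estimate is `first - second`. Defaults to the sorted unique levels.
#' @param transform `"auto"` (default), `"none"` or `"log"`.
#' @return A one-row tibble: `method`, `measure`, `conditions`,
#'   `transform`, `estimate` (mean paired difference on the analysis
#'   scale), `statistic`, `df`, `p.value`, `n_pairs`, `note`.
#' @export
paired_compare <- function(summaries, measure, conditions = NULL,
                           transform = c("auto", "none", "log")) {
  transform <- match.arg(transform)
  measure_name <- rlang::as_name(rlang::enquo(measure))
  df <- summaries |>
    select(participant_id, condition, value = {{ measure }}) |>
    filter(!is.na(value))
  levs <- conditions %||% sort(unique(df$condition))
  if (length(levs) != 2) {
    abort("paired_compare needs exactly 2 condition levels")
  }
  wide <- df |>
    filter(condition %in% levs) |>
    tidyr::pivot_wider(names_from = condition, values_from = value)
  unmatched <- wide$participant_id[!complete.cases(wide[levs])]
  if (length(unmatched) > 0) {
    abort(sprintf("participants without both conditions: %s",
                  paste(unmatched, collapse = ", ")))
  }
  a <- wide[[levs[1]]]
  b <- wide[[levs[2]]]
  applied <- "none"
  if (transform == "log" ||
      (transform == "auto" && length(a) >= 3 && length(a) <= 5000 &&
       all(c(a, b) > 0) && sd(a) > 0 && sd(b) > 0 &&
       (shapiro.test(a)$p.value < 0.05 || shapiro.test(b)$p.value < 0.05))) {
    if (all(c(a, b) > 0)) {
      a <- log(a); b <- log(b)
      applied <- "log"
    } else if (transform == "log") {
      abort("log transform requires strictly positive values")
    }
  }
  d <- a - b
  if (sd(d) == 0) {
    warn("zero-variance paired differences; t statistic undefined")
    return(tibble(
      method = "paired t", measure = measure_name,
      conditions = paste(levs, collapse = " - "), transform = applied,
      estimate = mean(d), statistic = NA_real_, df = NA_real_,
      p.value = NA_real_, n_pairs = length(d),
      note = "zero-variance differences"
    ))
  }
  tt <- t.test(a, b, paired = TRUE)
  tibble(
    method = "paired t", measure = measure_name,
    conditions = paste(levs, collapse = " - "), transform = applied,
    estimate = unname(tt$estimate), statistic = unname(tt$statistic),
    df = unname(tt$parameter), p.value = tt$p.value,
    n_pairs = length(d), note = NA_character_
  )
}

#' Ordinary least squares of motivation on the three task measures
#'
#' Gaussian GLM predicting the motivation score from fluency, mean
#' uniqueness and exploration area jointly, to ask which of the correlated
#' measures carries independent information about motivation.
#'
#' @param summaries Session summaries with `motivation`, `fluency`,
#'   `mean_uniqueness` and `hull_area` columns.
#' @return A tidy coefficient tibble.
#' @export
motivation_glm <- function(summaries) {
  assert_columns(summaries, c("motivation", "fluency", "mean_uniqueness",
                              "hull_area"), "summary table")
  fit <- lm(motivation ~ fluency + mean_uniqueness + hull_area,
            data = summaries)
  co <- as.data.frame(coef(summary(fit)))
  tibble(
    term = rownames(co),
    estimate = co[["Estimate"]],
    std.error = co[["Std. Error"]],
    statistic = co[["t value"]],
    p.value = co[["Pr(>|t|)"]],
    method = "gaussian GLM (OLS)"
  )
}
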