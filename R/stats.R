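#' Per-zone failure summary across sessions
#'
#' Assigns every ground-truth failure to its task zone and summarizes, per
#' subject: mean and standard deviation of failures per task (overall and
#' by zone), and a map of mean failure counts over zone-normalized time —
#' each failure mapped to `(zone, (t - zone_start) / zone_duration)` and
#' binned, so tasks of different durations are comparable.
#'
#' @param sessions A `myo_session` or a list of them (one or more per
#'   subject; subjects are read from the sessions).
#' @param n_bins Number of normalized-time bins per zone.
#' @return An object of class `myo_zone_summary`: list with `per_task`
#'   (tibble subject, task, zone counts), `summary` (tibble subject, zone
#'   incl. `"OVERALL"`, mean, sd) and `histogram` (tibble subject, zone,
#'   bin, mean count per task).
#' @export
zone_failure_summary <- function(sessions, n_bins = 10) {
  if (inherits(sessions, "myo_session")) sessions <- list(sessions)
  per_task <- list()
  hist_rows <- list()
  for (s in sessions) {
    tasks <- s$tasks
    if (!nrow(tasks)) abort("sessions must contain at least one task")
    durs <- cbind(
      tasks$t_grasp - tasks$t_start,
      tasks$t_release - tasks$t_grasp,
      tasks$t_end - tasks$t_release
    )
    if (any(durs <= 0)) abort("zero-duration task zone")
    ft <- s$failures$time
    ti <- task_index_of(ft, tasks)
    if (any(is.na(ti))) abort("failure outside every task span")
    zone <- character(length(ft))
    u <- numeric(length(ft))
    for (j in seq_along(ft)) {
      tl <- tasks[ti[j], ]
      zone[j] <- zone_of(ft[j], tl)
      zs <- switch(zone[j],
        PRE_GRASP = c(tl$t_start, tl$t_grasp),
        GRASP = c(tl$t_grasp, tl$t_release),
        POST_GRASP = c(tl$t_release, tl$t_end)
      )
      u[j] <- (ft[j] - zs[1]) / (zs[2] - zs[1])
    }
    counts <- tibble(
      subject = s$subject_id,
      task = seq_len(nrow(tasks)),
      PRE_GRASP = 0, GRASP = 0, POST_GRASP = 0
    )
    for (j in seq_along(ft)) {
      counts[[zone[j]]][ti[j]] <- counts[[zone[j]]][ti[j]] + 1
    }
    per_task[[length(per_task) + 1]] <- counts
    bin <- pmin(pmax(ceiling(u * n_bins), 1L), n_bins)
    hist_rows[[length(hist_rows) + 1]] <- tibble(
      subject = s$subject_id, zone = zone, bin = as.integer(bin),
      n_tasks = nrow(tasks)
    )
  }
  per_task <- dplyr::bind_rows(per_task)
  per_task <- per_task |>
    dplyr::group_by(.data$subject, .data$task) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(TASK_ZONES), sum), .groups = "drop")
  long <- per_task |>
    tidyr::pivot_longer(dplyr::all_of(TASK_ZONES),
      names_to = "zone", values_to = "n"
    )
  summary <- dplyr::bind_rows(
    long |>
      dplyr::group_by(.data$subject, .data$zone) |>
      dplyr::summarise(mean = mean(.data$n), sd = sd(.data$n), .groups = "drop"),
    long |>
      dplyr::group_by(.data$subject, .data$task) |>
      dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
      dplyr::group_by(.data$subject) |>
      dplyr::summarise(
        zone = "OVERALL", mean = mean(.data$n), sd = sd(.data$n),
        .groups = "drop"
      )
  ) |>
    dplyr::mutate(zone = factor(.data$zone, levels = c(TASK_ZONES, "OVERALL"))) |>
    dplyr::arrange(.data$subject, .data$zone)
  hist_long <- dplyr::bind_rows(hist_rows)
  grid <- tidyr::expand_grid(
    subject = unique(vapply(sessions, function(s) s$subject_id, character(1))),
    zone = TASK_ZONES, bin = seq_len(n_bins)
  )
  n_tasks_by_subject <- hist_long |>
    dplyr::distinct(.data$subject, .data$n_tasks)
  histogram <- hist_long |>
    dplyr::count(.data$subject, .data$zone, .data$bin) |>
    dplyr::right_join(grid, by = c("subject", "zone", "bin")) |>
    dplyr::left_join(n_tasks_by_subject, by = "subject") |>
    dplyr::mutate(
      mean_count = dplyr::coalesce(.data$n, 0L) / .data$n_tasks,
      zone = factor(.data$zone, levels = TASK_ZONES)
    ) |>
    dplyr::arrange(.data$subject, .data$zone, .data$bin) |>
    dplyr::select("subject", "zone", "bin", "mean_count")
  structure(
    list(per_task = per_task, summary = summary, histogram = histogram),
    class = "myo_zone_summary"
  )
}

#' @export
print.myo_zone_summary <- function(x, ...) {
  cat("<myo_zone_summary>\n")
  print(x$summary)
  invisible(x)
}

#' Least-squares trend with Cook's distances
#'
#' Fits an ordinary least-squares line through `(x, y)` points and computes
#' each point's Cook's distance, the standard leverage/residual measure of
#' its influence on the fit (equal to the scaled change in fitted values
#' when the point is left out and the model refit).
#'
#' @param points Data frame with numeric columns `x` and `y` (at least
#'   three rows, non-constant `x`).
#' @return An object of class `myo_trend`: list with `intercept`, `slope`
#'   and `diagnostics` (tibble `x`, `y`, `fitted`, `residual`, `cooks_d`).
#' @export
trend_with_cooks <- function(points) {
  if (nrow(points) < 3) abort("at least three points are required")
  if (var(points$x) == 0) abort("singular fit: all x values are equal")
  fit <- lm(y ~ x, data = points)
  cd <- unname(cooks.distance(fit))
  # an exact fit has zero influence everywhere; avoid the 0/0 of the
  # standardized form
  sigma <- suppressWarnings(summary(fit)$sigma)
  if (sigma <= 1e-10 * (sd(points$y) + 1e-300)) {
    cd <- rep(0, nrow(points))
  }
  structure(
    list(
      intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
      diagnostics = tibble(
        x = points$x, y = points$y,
        fitted = unname(fit$fitted.values),
        residual = unname(fit$residuals),
        cooks_d = cd
      )
    ),
    class = "myo_trend"
  )
}

#' @export
print.myo_trend <- function(x, ...) {
  cat(sprintf(
    "<myo_trend> y = %.4f + %.4f x; max Cook's distance %.4f\n",
    x$intercept, x$slope, max(x$diagnostics$cooks_d)
  ))
  invisible(x)
}

#' Compare two groups of balanced error rates
#'
#' Assesses per-group normality with the Shapiro-Wilk test and compares the
#' groups with the two-sided Wilcoxon rank-sum test (exact when the
#' combined sample is small and untied, normal approximation with
#' continuity correction otherwise). The reported `W` is the rank sum of
#' the first group.
#'
#' @param a,b Numeric vectors (each of length at least 3).
#' @param exact_max Combined sample size up to which the exact rank-sum
#'   distribution is used (in the absence of ties).
#' @return Tibble with `shapiro_p_a`, `shapiro_p_b`, `w`, `p`.
#' @export
compare_groups <- function(a, b, exact_max = 25) {
  if (length(a) < 3 || length(b) < 3) {
    abort("each group needs at least three observations")
  }
  exact <- (length(a) + length(b)) <= exact_max && !any(duplicated(c(a, b)))
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  tibble(
    shapiro_p_a = shapiro.test(a)$p.value,
    shapiro_p_b = shapiro.test(b)$p.value,
    w = unname(wt$statistic) + length(a) * (length(a) + 1) / 2,
    p = wt$p.value
  )
}

#' Factorial ANOVA of balanced error rates
#'
#' Runs the three-way fixed-effects ANOVA (all main effects and
#' interactions) of BER on feature type, window length and window overlap,
#' on the balanced full-factorial table of one BER per subject and
#' condition. The model is then reduced to the single factor feature type
#' (one-way ANOVA) and followed up with Tukey HSD pairwise comparisons of
#' the feature types. Unbalanced tables are rejected — on the balanced
#' design the classical sequential sums of squares equal the partial ones.
#'
#' @param data Data frame with columns `subject`, `feature_type`,
#'   `window_length`, `overlap` and `ber`.
#' @return An object of class `myo_anova`: list with `three_way` and
#'   `one_way` effect tibbles (`term`, `df`, `df_resid`, `ss`, `f`, `p`)
#'   and `tukey` (tibble `contrast`, `diff`, `lwr`, `upr`, `p_adj`).
#' @export
anova_ber <- function(data) {
  req <- c("subject", "feature_type", "window_length", "overlap", "ber")
  if (!all(req %in% names(data))) {
    abort("data needs columns subject, feature_type, window_length, overlap, ber")
  }
  d <- data
  d$feature_type <- factor(d$feature_type)
  d$window_length <- factor(d$window_length)
  d$overlap <- factor(d$overlap)
  cell_n <- table(d$feature_type, d$window_length, d$overlap)
  if (length(unique(as.vector(cell_n))) != 1 || any(cell_n == 0)) {
    abort("unbalanced design: every feature x window x overlap cell needs the same count")
  }
  fit3 <- aov(ber ~ feature_type * window_length * overlap, data = d)
  fit1 <- aov(ber ~ feature_type, data = d)
  tuk <- TukeyHSD(fit1, "feature_type")$feature_type
  null_response <- var(d$ber) == 0
  structure(
    list(
      three_way = aov_effects(fit3, null_response),
      one_way = aov_effects(fit1, null_response),
      tukey = tibble(
        contrast = rownames(tuk),
        diff = tuk[, "diff"], lwr = tuk[, "lwr"], upr = tuk[, "upr"],
        p_adj = tuk[, "p adj"]
      )
    ),
    class = "myo_anova"
  )
}

aov_effects <- function(fit, null_response = FALSE) {
  sm <- summary(fit)[[1]]
  term <- trimws(rownames(sm))
  resid_row <- term == "Residuals"
  df_resid <- as.integer(sm$Df[resid_row])
  f <- sm$`F value`
  p <- sm$`Pr(>F)`
  # a constant response carries no effect: report F = 0 rather than 0/0
  zero <- if (null_response) !resid_row else sm$`Sum Sq` == 0 & !resid_row
  f[zero] <- 0
  p[zero] <- 1
  tibble(
    term = term[!resid_row],
    df = as.integer(sm$Df[!resid_row]),
    df_resid = df_resid,
    ss = sm$`Sum Sq`[!resid_row],
    ss_resid = sm$`Sum Sq`[resid_row],
    f = f[!resid_row],
    p = p[!resid_row]
  )
}

#' @export
print.myo_anova <- function(x, ...) {
  cat("<myo_anova> three-way effects:\n")
  print(x$three_way)
  cat("Tukey HSD on feature type:\n")
  print(x$tukey)
  invisible(x)
}
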