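# Hand-built miniature session: constant rest prediction except where a
# test overrides it; statuses all OPEN. Tasks tile the span evenly.
toy_session <- function(n_tasks = 3, rate = 100, span = 60,
                        pred_level = 0.05, failures = NULL) {
  time <- seq(0, span, by = 1 / rate)
  pred <- tibble::tibble(
    time = time,
    p1 = rep(pred_level, length(time)), p2 = rep(pred_level, length(time)),
    p3 = rep(pred_level, length(time)), p4 = rep(pred_level, length(time))
  )
  stat <- tibble::tibble(time = time)
  for (d in 1:6) stat[[paste0("d", d)]] <- rep("OPEN", length(time))
  len <- span / n_tasks
  tasks <- tibble::tibble(
    t_start = (seq_len(n_tasks) - 1) * len,
    t_grasp = (seq_len(n_tasks) - 1) * len + len * 0.3,
    t_release = (seq_len(n_tasks) - 1) * len + len * 0.6,
    t_end = seq_len(n_tasks) * len
  )
  # shrink last task end so spans don't touch the next start exactly
  myo_session(
    prediction = pred, digit_status = stat, tasks = tasks,
    failures = failures, subject_id = "TOY", sample_rate = rate
  )
}

# Small, fast simulator settings used where full-scale sessions are not the
# point of the test.
small_sim <- function(seed = 1, n_tasks = 4, ...) {
  sim_config(seed = seed, n_tasks = n_tasks, sample_rate = 50, ...)
}

# Compact hyperparameter grids: nested-CV mechanics do not need the full
# libsvm sweep.
tiny_grid <- list(cost = c(1, 100), gamma = c(0.01, 0.25))

# Linearly separable two-class feature clouds (4-d), labels 0/1.
gaussian_clouds <- function(n0 = 60, n1 = 40, shift = 4, sd = 1) {
  x <- rbind(
    matrix(rnorm(n0 * 4, 0, sd), ncol = 4),
    matrix(rnorm(n1 * 4, shift, sd), ncol = 4)
  )
  d <- tibble::as_tibble(as.data.frame(x))
  names(d) <- paste0("f", 1:4)
  d$label <- c(rep(0L, n0), rep(1L, n1))
  d
}

# All-pairs Mann-Whitney AUC oracle, ties counted one half. Success
# (label 0) is the positive condition and higher scores favour success.
auc_pairs_oracle <- function(scores, labels) {
  s_pos <- scores[labels == 0]
  s_neg <- scores[labels == 1]
  tot <- 0
  for (a in s_pos) {
    for (b in s_neg) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
  }
  tot / (length(s_pos) * length(s_neg))
}

# Cook's distance by brute-force leave-one-out refits.
cooks_loo_oracle <- function(x, y) {
  fit <- lm(y ~ x)
  yhat <- fitted(fit)
  p <- 2
  s2 <- sum(residuals(fit)^2) / (length(x) - p)
  vapply(seq_along(x), function(i) {
    fit_i <- lm(y[-i] ~ x[-i])
    yhat_i <- cbind(1, x) %*% coef(fit_i)
    sum((yhat - yhat_i)^2) / (p * s2)
  }, numeric(1))
}

# Balanced full-factorial BER table (subjects x 3 feature types x 3 window
# lengths x 2 overlaps) with an additive feature-type effect.
synthetic_ber_table <- function(n_subjects = 6, shift = c(tc = 10, sc = 0, tcsc = 0),
                                noise_sd = 1) {
  d <- tidyr::expand_grid(
    subject = sprintf("S%d", seq_len(n_subjects)),
    feature_type = c("tc", "sc", "tcsc"),
    window_length = c(0.5, 1, 3),
    overlap = c("none", "half")
  )
  d$ber <- 20 + shift[d$feature_type] + rnorm(nrow(d), 0, noise_sd)
  d
}
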