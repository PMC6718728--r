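test_that("zone summary assigns failures to zones and normalized-time bins", {
  # one failure per task at the grasp midpoint
  s <- toy_session(n_tasks = 5, rate = 20, span = 100)
  mid <- (s$tasks$t_grasp + s$tasks$t_release) / 2
  s$failures <- tibble::tibble(
    time = mid, channel = rep(1L, 5), kind = rep("SPURIOUS_OPEN", 5)
  )
  zs <- zone_failure_summary(s)
  sm <- zs$summary
  expect_equal(sm$mean[sm$zone == "GRASP"], 1)
  expect_equal(sm$sd[sm$zone == "GRASP"], 0)
  expect_equal(sm$mean[sm$zone == "PRE_GRASP"], 0)
  expect_equal(sm$mean[sm$zone == "POST_GRASP"], 0)
  # per-zone means sum to the overall mean
  expect_equal(
    sum(sm$mean[sm$zone != "OVERALL"]),
    sm$mean[sm$zone == "OVERALL"]
  )
  # the grasp midpoint lands mid-histogram
  h <- zs$histogram
  grasp_bins <- h[h$zone == "GRASP" & h$mean_count > 0, ]
  expect_identical(grasp_bins$bin, 5L)
  expect_equal(grasp_bins$mean_count, 1)
})

test_that("uniform failures fill the normalized histogram flatly", {
  s <- toy_session(n_tasks = 40, rate = 10, span = 400)
  n_per_task <- 6
  withr::local_seed(8)
  ft <- unlist(lapply(seq_len(40), function(k) {
    runif(n_per_task, s$tasks$t_release[k], s$tasks$t_end[k] - 1e-6)
  }))
  s$failures <- tibble::tibble(
    time = ft, channel = rep(1L, length(ft)), kind = rep("SPURIOUS_CLOSE", length(ft))
  )
  h <- zone_failure_summary(s)$histogram
  post <- h[h$zone == "POST_GRASP", ]
  counts <- post$mean_count * 40
  n_tot <- 40 * n_per_task
  expected <- n_tot / 10
  sigma <- sqrt(n_tot * (1 / 10) * (9 / 10))
  expect_true(all(abs(counts - expected) < 3 * sigma))
  expect_equal(sum(counts), n_tot)
})

test_that("zone summary sums across sessions of the same subject", {
  a <- generate_session(small_sim(seed = 61))
  b <- generate_session(small_sim(seed = 62))
  zs <- zone_failure_summary(list(a, b))
  expect_identical(nrow(zs$per_task), nrow(a$tasks))
  overall <- zs$summary$mean[zs$summary$zone == "OVERALL"]
  expect_equal(overall * nrow(a$tasks), nrow(a$failures) + nrow(b$failures))
})

test_that("Cook's distances match leave-one-out refits", {
  # collinear points: zero residuals, zero distances
  tr <- trend_with_cooks(tibble::tibble(x = 1:5, y = 2 + 3 * (1:5)))
  expect_equal(tr$slope, 3)
  expect_equal(tr$intercept, 2)
  expect_equal(tr$diagnostics$residual, rep(0, 5))
  expect_equal(tr$diagnostics$cooks_d, rep(0, 5))
  withr::with_seed(13, {
    for (rep in 1:10) {
      n <- sample(8:30, 1)
      x <- rnorm(n)
      y <- 1 + 0.5 * x + rnorm(n)
      tr <- trend_with_cooks(tibble::tibble(x = x, y = y))
      expect_equal(tr$diagnostics$cooks_d, cooks_loo_oracle(x, y), tolerance = 1e-10)
    }
  })
  expect_error(trend_with_cooks(tibble::tibble(x = c(1, 1, 1), y = 1:3)), "singular")
  expect_error(trend_with_cooks(tibble::tibble(x = 1:2, y = 1:2)), "three points")
})

test_that("duplicating a point changes its influence per the closed form", {
  withr::local_seed(3)
  x <- c(rnorm(10), 4)
  y <- 1 + x + rnorm(11, 0, 0.5)
  base <- trend_with_cooks(tibble::tibble(x = x, y = y))
  dup <- trend_with_cooks(tibble::tibble(x = c(x, 4), y = c(y, y[11])))
  expect_equal(dup$diagnostics$cooks_d, cooks_loo_oracle(c(x, 4), c(y, y[11])),
    tolerance = 1e-10
  )
  expect_lt(dup$diagnostics$cooks_d[12], base$diagnostics$cooks_d[11])
})

test_that("group comparison reports rank-sum W and exact small-sample p", {
  g <- compare_groups(c(1, 2, 3), c(10, 11, 12))
  expect_equal(g$w, 6) # minimal possible rank sum of the first group
  expect_equal(g$p, 2 / choose(6, 3)) # exhaustive permutation: 2/20
  # symmetric interleaving: rank sum equals its null expectation
  same <- compare_groups(c(1, 4, 5, 8), c(2, 3, 6, 7))
  expect_equal(same$w, 18)
  expect_gt(same$p, 0.9)
  withr::local_seed(9)
  a <- rnorm(50)
  b <- rnorm(60)
  g2 <- compare_groups(a, b)
  expect_true(g2$shapiro_p_a > 0 && g2$shapiro_p_a < 1)
  expect_true(g2$p > 0 && g2$p <= 1)
  # W on the rank-sum scale: between minimal and maximal possible values
  expect_gte(g2$w, 50 * 51 / 2)
  expect_lte(g2$w, 50 * (50 + 2 * 60 + 1) / 2)
  expect_error(compare_groups(c(1, 2), c(3, 4, 5)), "three")
})

test_that("three-way ANOVA has the factorial degrees of freedom", {
  d <- withr::with_seed(21, synthetic_ber_table(n_subjects = 6, shift = c(tc = 0, sc = 0, tcsc = 0)))
  a <- anova_ber(d)
  tw <- a$three_way
  expect_identical(tw$df[tw$term == "feature_type"], 2L)
  expect_identical(tw$df[tw$term == "window_length"], 2L)
  expect_identical(tw$df[tw$term == "overlap"], 1L)
  expect_true(all(tw$df_resid == 90L))
  ow <- a$one_way
  expect_identical(ow$df[ow$term == "feature_type"], 2L)
  expect_true(all(ow$df_resid == 105L))
  # SS decomposition: effects + residual = total
  expect_equal(
    sum(tw$ss) + tw$ss_resid[1],
    sum((d$ber - mean(d$ber))^2)
  )
})

test_that("a constructed feature-type effect is recovered and localized by Tukey", {
  d <- withr::with_seed(77, synthetic_ber_table(n_subjects = 6, shift = c(tc = 10, sc = 0, tcsc = 0)))
  a <- anova_ber(d)
  p_ft <- a$three_way$p[a$three_way$term == "feature_type"]
  expect_lt(p_ft, 0.001)
  tuk <- a$tukey
  parts <- strsplit(tuk$contrast, "-")
  tc_rows <- vapply(parts, function(p) "tc" %in% p, logical(1))
  expect_true(all(tuk$p_adj[tc_rows] < 0.001))
  sc_tcsc <- vapply(parts, function(p) setequal(p, c("sc", "tcsc")), logical(1))
  expect_true(all(tuk$p_adj[sc_tcsc] > 0.05))
})

test_that("identical responses yield null F statistics, unbalanced tables error", {
  d <- synthetic_ber_table(n_subjects = 2, shift = c(tc = 0, sc = 0, tcsc = 0), noise_sd = 0)
  d$ber <- 5
  a <- anova_ber(d)
  expect_true(all(a$three_way$f == 0))
  expect_true(all(a$one_way$f == 0))
  expect_error(anova_ber(d[-1, ]), "unbalanced")
})

test_that("cohens_f_from_ss is the square-root SS ratio", {
  expect_equal(cohens_f_from_ss(100, 100), 1)
  expect_equal(cohens_f_from_ss(0, 10), 0)
  expect_equal(cohens_f_from_ss(25, 100), 0.5)
  expect_error(cohens_f_from_ss(1, 0), "positive")
  expect_error(cohens_f_from_ss(-1, 10), "non-negative")
})
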