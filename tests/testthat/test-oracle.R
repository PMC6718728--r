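test_that("class weights up-weight the failure minority by n0/n1", {
  w <- class_weights(c(rep(0, 900), rep(1, 100)))
  expect_equal(w$c_failure, 9)
  expect_identical(c(w$n0, w$n1), c(900L, 100L))
  expect_equal(class_weights(c(rep(0, 50), rep(1, 50)))$c_failure, 1)
  expect_error(class_weights(rep(0, 100)), "degenerate")
  expect_error(class_weights(rep(1, 5)), "degenerate")
})

test_that("rate matrix implements the row-normalized occurrence rates", {
  r <- rate_matrix(list(n_tp = 8, n_fp = 2, n_fn = 1, n_tn = 9))
  expect_equal(r$tpr, 8 / 9)
  expect_equal(r$fpr, 2 / 11)
  expect_equal(r$fnr, 1 - r$tpr)
  expect_equal(r$tnr, 1 - r$fpr)
  perfect <- rate_matrix(list(n_tp = 12, n_fp = 0, n_fn = 0, n_tn = 5))
  expect_equal(c(perfect$tpr, perfect$fpr), c(1, 0))
  all_succ <- rate_matrix(list(n_tp = 12, n_fp = 5, n_fn = 0, n_tn = 0))
  expect_equal(c(all_succ$tpr, all_succ$fpr), c(1, 1))
  expect_error(rate_matrix(list(n_tp = 0, n_fp = 2, n_fn = 0, n_tn = 9)), "undefined")
})

test_that("balanced error rate matches its closed form and invariances", {
  expect_equal(ber(list(n_tp = 10, n_fp = 0, n_fn = 0, n_tn = 4)), 0)
  expect_equal(ber(list(n_tp = 10, n_fp = 4, n_fn = 0, n_tn = 0)), 50)
  expect_equal(
    ber(list(n_tp = 8, n_fp = 2, n_fn = 1, n_tn = 9)),
    100 / 2 * (1 / 9 + 2 / 11)
  )
  withr::with_seed(5, {
    for (rep in 1:25) {
      m <- list(
        n_tp = sample(1:50, 1), n_fp = sample(0:50, 1),
        n_fn = sample(0:50, 1), n_tn = sample(1:50, 1)
      )
      r <- rate_matrix(m)
      # two code paths agree exactly
      expect_equal(ber(m), 100 * (r$fnr + r$fpr) / 2)
      # scale invariance per condition row
      m2 <- list(
        n_tp = 3 * m$n_tp, n_fn = 3 * m$n_fn,
        n_fp = 7 * m$n_fp, n_tn = 7 * m$n_tn
      )
      expect_equal(ber(m2), ber(m))
    }
  })
})

test_that("AUC equals the all-pairs Mann-Whitney oracle, ties counted half", {
  expect_equal(roc_auc(c(4, 3, 2, 1), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 0)
  tied <- roc_auc(c(1, 2, 2, 3), c(0, 0, 1, 1))
  expect_equal(tied$auc, auc_pairs_oracle(c(1, 2, 2, 3), c(0, 0, 1, 1)))
  withr::with_seed(11, {
    for (rep in 1:10) {
      n <- sample(10:60, 1)
      labels <- c(rep(0, n), rep(1, n))
      scores <- sample(1:8, 2 * n, replace = TRUE) + rnorm(2 * n, 0, 0.01)
      expect_equal(roc_auc(scores, labels)$auc, auc_pairs_oracle(scores, labels))
      # invariance under strictly monotone transforms of the scores
      expect_equal(
        roc_auc(exp(scores / 3), labels)$auc,
        roc_auc(scores, labels)$auc
      )
    }
  })
  expect_error(roc_auc(1:5, rep(0, 5)), "both classes")
})

test_that("the ROC curve agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(3, {
    scores <- c(rnorm(40, 1), rnorm(30, 0))
    labels <- c(rep(0, 40), rep(1, 30))
  })
  mine <- roc_auc(scores, labels)
  ref <- pROC::roc(
    response = labels, predictor = scores, levels = c("1", "0"),
    direction = "<", quiet = TRUE
  )
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)))
})

test_that("mean ROC vertically averages interpolated curves", {
  curve <- tibble::tibble(fpr = c(0, 0.2, 1), tpr = c(0, 0.8, 1))
  single <- mean_roc(list(curve))
  expect_equal(
    single$tpr[single$fpr == 0.2], 0.8
  )
  expect_identical(nrow(single), 101L)
  two <- mean_roc(list(curve, curve))
  expect_equal(two$tpr, single$tpr)
  diagonal <- tibble::tibble(fpr = c(0, 1), tpr = c(0, 1))
  step <- tibble::tibble(fpr = c(0, 0, 1), tpr = c(0, 1, 1))
  m <- mean_roc(list(diagonal, step))
  expect_equal(m$tpr[m$fpr == 0.5], (0.5 + 1) / 2)
})

test_that("nested CV separates seeded Gaussian clouds and stays at chance on noise", {
  d <- withr::with_seed(101, gaussian_clouds(n0 = 60, n1 = 40, shift = 4))
  cv <- nested_cv(d,
    grid_cost = tiny_grid$cost, grid_gamma = tiny_grid$gamma, seed = 1
  )
  expect_lt(cv$ber, 5)
  expect_gt(cv$auc, 0.95)
  d_null <- withr::with_seed(202, {
    x <- gaussian_clouds(n0 = 50, n1 = 50, shift = 0)
    x$label <- sample(x$label)
    x
  })
  cv0 <- nested_cv(d_null,
    grid_cost = tiny_grid$cost, grid_gamma = tiny_grid$gamma, seed = 2
  )
  expect_gte(cv0$ber, 40)
  expect_lte(cv0$ber, 60)
})

test_that("nested CV is deterministic and pools fold confusions exactly", {
  d <- withr::with_seed(55, gaussian_clouds(n0 = 40, n1 = 30, shift = 2))
  cv1 <- nested_cv(d, grid_cost = tiny_grid$cost, grid_gamma = tiny_grid$gamma, seed = 9)
  cv2 <- nested_cv(d, grid_cost = tiny_grid$cost, grid_gamma = tiny_grid$gamma, seed = 9)
  expect_identical(unclass(cv1), unclass(cv2))
  expect_identical(nrow(cv1$folds), 10L)
  expect_identical(sum(cv1$folds$n_tp), cv1$pooled$n_tp)
  expect_identical(sum(cv1$folds$n_fp), cv1$pooled$n_fp)
  expect_identical(sum(cv1$folds$n_fn), cv1$pooled$n_fn)
  expect_identical(sum(cv1$folds$n_tn), cv1$pooled$n_tn)
  expect_identical(
    cv1$pooled$n_tp + cv1$pooled$n_fp + cv1$pooled$n_fn + cv1$pooled$n_tn,
    nrow(d)
  )
  # fold sizes differ across seeds but results remain valid
  cv3 <- nested_cv(d, grid_cost = tiny_grid$cost, grid_gamma = tiny_grid$gamma, seed = 10)
  expect_false(identical(cv1$scores$score, cv3$scores$score))
  g <- glance(cv1)
  expect_equal(g$ber, cv1$ber)
  expect_identical(nrow(tidy(cv1)), 10L)
})

test_that("nested CV rejects datasets too degenerate to stratify", {
  d <- withr::with_seed(1, gaussian_clouds(n0 = 40, n1 = 5))
  expect_error(nested_cv(d, seed = 1), "degenerate")
})

test_that("raising the failure weight weakly increases detected failures", {
  d <- withr::with_seed(77, gaussian_clouds(n0 = 80, n1 = 20, shift = 1.2, sd = 1.5))
  x <- scale(as.matrix(d[paste0("f", 1:4)]))
  detected <- vapply(c(0.25, 1, 4, 16, 64), function(w) {
    fit <- myoracle:::fit_wsvm(x, d$label, cost = 1, gamma = 0.25, weight_failure = w)
    sum(myoracle:::predict_wsvm(fit, x)$label)
  }, numeric(1))
  expect_true(all(diff(detected) >= 0))
  expect_gt(detected[5], detected[1])
})
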