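#' Class weights for the imbalance-aware SVM
#'
#' The success class (label 0, the majority) keeps weight 1 while the
#' failure class (label 1, the minority) is up-weighted by the class ratio
#' `n0 / n1`, the standard remedy for skewed class proportions in a
#' class-weighted SVM.
#'
#' @param labels Integer/logical vector of window labels (0 = success,
#'   1 = failure).
#' @return List with `c_success` (= 1), `c_failure` (= n0/n1), `n0`, `n1`.
#' @examples
#' class_weights(c(rep(0, 900), rep(1, 100)))
#' @export
class_weights <- function(labels) {
  labels <- as.integer(labels)
  n0 <- sum(labels == 0L)
  n1 <- sum(labels == 1L)
  if (n0 == 0L || n1 == 0L) {
    abort("degenerate dataset: both success and failure labels are required")
  }
  list(c_success = 1, c_failure = n0 / n1, n0 = n0, n1 = n1)
}

#' Confusion matrix with success as the positive condition
#'
#' Tallies prediction outcomes under the convention that a myocontrol
#' *success* is the positive condition and a *failure* the negative one.
#'
#' @param truth,predicted Integer vectors of labels (0 = success,
#'   1 = failure).
#' @return List with counts `n_tp`, `n_fp`, `n_fn`, `n_tn`.
#' @export
confusion_matrix <- function(truth, predicted) {
  truth <- as.integer(truth)
  predicted <- as.integer(predicted)
  list(
    n_tp = sum(predicted == 0L & truth == 0L),
    n_fp = sum(predicted == 0L & truth == 1L),
    n_fn = sum(predicted == 1L & truth == 0L),
    n_tn = sum(predicted == 1L & truth == 1L)
  )
}

#' Occurrence-rate matrix of a confusion matrix
#'
#' Row-normalizes the counts: `tpr = n_tp / (n_tp + n_fn)`,
#' `fpr = n_fp / (n_fp + n_tn)`, with `fnr` and `tnr` their complements.
#'
#' @param m Confusion counts (list with `n_tp`, `n_fp`, `n_fn`, `n_tn`).
#' @return List with `tpr`, `fpr`, `fnr`, `tnr`.
#' @examples
#' rate_matrix(list(n_tp = 8, n_fp = 2, n_fn = 1, n_tn = 9))
#' @export
rate_matrix <- function(m) {
  p <- m$n_tp + m$n_fn
  n <- m$n_fp + m$n_tn
  if (p == 0) abort("undefined rate: no positive-condition (success) instances")
  if (n == 0) abort("undefined rate: no negative-condition (failure) instances")
  list(tpr = m$n_tp / p, fpr = m$n_fp / n, fnr = m$n_fn / p, tnr = m$n_tn / n)
}

#' Balanced error rate
#'
#' `BER = 100/2 * (n_fn/(n_tp + n_fn) + n_fp/(n_fp + n_tn))`, i.e. the mean
#' of the false-negative and false-positive rates as a percentage — an
#' error measure robust to class imbalance.
#'
#' @param m Confusion counts (list with `n_tp`, `n_fp`, `n_fn`, `n_tn`).
#' @return BER in \[0, 100\].
#' @examples
#' ber(list(n_tp = 8, n_fp = 2, n_fn = 1, n_tn = 9))
#' @export
ber <- function(m) {
  r <- rate_matrix(m)
  100 / 2 * (r$fnr + r$fpr)
}

#' ROC curve and AUC from decision scores
#'
#' Sweeps the decision criterion over all score thresholds, with the
#' success class (label 0) as the positive condition and higher scores
#' meaning more success-like. The AUC is computed by the rank (Mann-Whitney)
#' formula, so tied scores count one half.
#'
#' @param scores Numeric decision values.
#' @param labels Labels (0 = success, 1 = failure); both classes required.
#' @return List with `roc` (tibble `threshold`, `fpr`, `tpr`, including the
#'   (0,0) and (1,1) endpoints) and `auc`.
#' @examples
#' roc_auc(c(3, 2, 1, 0), c(0, 0, 1, 1))
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  pos <- labels == 0L
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) abort("both classes are required for a ROC curve")
  r <- rank(scores)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(p)[last_of_tie]
  fp <- cumsum(!p)[last_of_tie]
  roc <- tibble(
    threshold = c(Inf, s[last_of_tie]),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
  list(roc = roc, auc = auc)
}

#' Vertically average ROC curves
#'
#' Averages true-positive rates over a fixed grid of false-positive rates
#' (0 to 1 in 101 points), linearly interpolating each curve; vertical
#' segments contribute their upper envelope.
#'
#' @param curves List of ROC tibbles (columns `fpr`, `tpr`).
#' @return Tibble with columns `fpr`, `tpr` on the common grid.
#' @export
mean_roc <- function(curves) {
  if (is.data.frame(curves)) curves <- list(curves)
  if (!length(curves)) abort("at least one ROC curve is required")
  grid <- seq(0, 1, length.out = 101)
  tprs <- vapply(curves, function(cv) {
    approx(
      x = c(0, cv$fpr, 1), y = c(0, cv$tpr, 1), xout = grid,
      ties = max, rule = 2
    )$y
  }, numeric(101))
  tibble(fpr = grid, tpr = rowMeans(as.matrix(tprs)))
}

# Stratified k-fold assignment (labels 0/1); assumes RNG already seeded.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Standardize train columns to zero mean / unit variance using the training
# statistics only; constant columns are left centered.
scale_pair <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(
    train = sweep(sweep(train, 2, mu), 2, sdv, "/"),
    test = sweep(sweep(test, 2, mu), 2, sdv, "/")
  )
}

fit_wsvm <- function(x, y, cost, gamma, weight_failure = NULL) {
  if (is.null(weight_failure)) weight_failure <- class_weights(y)$c_failure
  e1071::svm(
    x = x, y = factor(y, levels = c(0L, 1L), labels = c("success", "failure")),
    type = "C-classification", kernel = "radial",
    cost = cost, gamma = gamma, scale = FALSE,
    class.weights = c(success = 1, failure = weight_failure)
  )
}

predict_wsvm <- function(model, x) {
  pr <- predict(model, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # orient scores so that higher = more success-like
  score <- if (grepl("^success/", colnames(dv)[1])) dv[, 1] else -dv[, 1]
  list(label = as.integer(pr == "failure"), score = as.numeric(score))
}

#' Nested cross-validation of the class-weighted SVM failure detector
#'
#' Evaluates the RBF-kernel, class-weighted SVM under a stratified nested
#' cross-validation: the inner 10-fold loop grid-searches `(cost, gamma)`
#' by mean inner balanced error rate (ties broken toward smaller cost, then
#' smaller gamma); the winning pair is refit on the outer training set —
#' with class weights from its labels and features standardized by its
#' statistics only — and applied to the held-out fold. Pooled outer-fold
#' predictions yield the confusion matrix, BER, ROC curve and AUC.
#'
#' @param data Feature dataset: a data frame with a `label` column
#'   (0 = success, 1 = failure); every other numeric column except `task`,
#'   `window_start` and `window_end` is used as a feature (the output of
#'   [extract_dataset()] works directly).
#' @param grid_cost,grid_gamma Hyperparameter grids (powers of four spanning
#'   the usual libsvm ranges by default).
#' @param k_outer,k_inner Fold counts of the outer and inner loops.
#' @param seed Integer seed controlling the fold shuffles; results are a
#'   deterministic function of `(data, grids, seed)`.
#' @return An object of class `myo_cv`: list with `folds` (per-outer-fold
#'   tibble of chosen hyperparameters and confusion counts), `pooled`
#'   confusion counts, `ber`, `roc`, `auc`, `scores` (pooled decision
#'   values with true labels) and `n`.
#' @export
nested_cv <- function(data, grid_cost = 2^seq(-5, 15, by = 2),
                      grid_gamma = 2^seq(-15, 3, by = 2),
                      k_outer = 10, k_inner = 10, seed = 1) {
  if (!"label" %in% names(data)) abort("data needs a 'label' column")
  labels <- as.integer(data$label)
  feat_cols <- setdiff(
    names(data)[vapply(data, is.numeric, logical(1))],
    c("task", "window_start", "window_end", "label")
  )
  if (!length(feat_cols)) abort("no feature columns found")
  x <- as.matrix(data[feat_cols])
  if (min(sum(labels == 0L), sum(labels == 1L)) < k_outer) {
    abort(sprintf(
      "degenerate dataset: need at least %d instances of each class", k_outer
    ))
  }
  withr::with_seed(seed, {
    outer_fold <- stratified_folds(labels, k_outer)
    fold_rows <- vector("list", k_outer)
    score_rows <- vector("list", k_outer)
    for (of in seq_len(k_outer)) {
      tr <- outer_fold != of
      x_tr <- x[tr, , drop = FALSE]
      y_tr <- labels[tr]
      inner_fold <- stratified_folds(y_tr, k_inner)
      pick <- grid_search_inner(x_tr, y_tr, inner_fold, grid_cost, grid_gamma, k_inner)
      sc <- scale_pair(x_tr, x[!tr, , drop = FALSE])
      model <- fit_wsvm(sc$train, y_tr, pick$cost, pick$gamma)
      pred <- predict_wsvm(model, sc$test)
      cm <- confusion_matrix(labels[!tr], pred$label)
      fold_rows[[of]] <- tibble(
        fold = of, cost = pick$cost, gamma = pick$gamma,
        inner_ber = pick$ber,
        n_tp = cm$n_tp, n_fp = cm$n_fp, n_fn = cm$n_fn, n_tn = cm$n_tn
      )
      score_rows[[of]] <- tibble(
        fold = of, score = pred$score, label = labels[!tr]
      )
    }
  })
  folds <- dplyr::bind_rows(fold_rows)
  scores <- dplyr::bind_rows(score_rows)
  pooled <- list(
    n_tp = sum(folds$n_tp), n_fp = sum(folds$n_fp),
    n_fn = sum(folds$n_fn), n_tn = sum(folds$n_tn)
  )
  rc <- roc_auc(scores$score, scores$label)
  structure(
    list(
      folds = folds, pooled = pooled, ber = ber(pooled),
      roc = rc$roc, auc = rc$auc, scores = scores, n = nrow(data),
      grid_cost = grid_cost, grid_gamma = grid_gamma, seed = seed
    ),
    class = "myo_cv"
  )
}

# Mean inner-fold BER per (cost, gamma); folds whose test part lacks a class
# contribute nothing. Grid iterated in (cost, gamma) ascending order so the
# first minimum wins the tie toward smoother models.
grid_search_inner <- function(x_tr, y_tr, inner_fold, grid_cost, grid_gamma, k_inner) {
  best <- list(cost = grid_cost[1], gamma = grid_gamma[1], ber = Inf)
  splits <- lapply(seq_len(k_inner), function(f) {
    tr <- inner_fold != f
    if (all(tr) || !any(tr)) {
      return(NULL)
    }
    if (length(unique(y_tr[tr])) < 2 || length(unique(y_tr[!tr])) < 2) {
      return(NULL)
    }
    sc <- scale_pair(x_tr[tr, , drop = FALSE], x_tr[!tr, , drop = FALSE])
    list(x_tr = sc$train, y_tr = y_tr[tr], x_te = sc$test, y_te = y_tr[!tr])
  })
  splits <- splits[!vapply(splits, is.null, logical(1))]
  if (!length(splits)) abort("degenerate dataset: no usable inner folds")
  for (cost in sort(grid_cost)) {
    for (gamma in sort(grid_gamma)) {
      bers <- vapply(splits, function(sp) {
        model <- fit_wsvm(sp$x_tr, sp$y_tr, cost, gamma)
        pred <- predict_wsvm(model, sp$x_te)
        ber(confusion_matrix(sp$y_te, pred$label))
      }, numeric(1))
      m <- mean(bers)
      if (m < best$ber - 1e-12) best <- list(cost = cost, gamma = gamma, ber = m)
    }
  }
  best
}

#' @export
print.myo_cv <- function(x, ...) {
  cat(sprintf(
    "<myo_cv> %d windows, %d outer folds: pooled BER %.2f%%, AUC %.4f\n",
    x$n, nrow(x$folds), x$ber, x$auc
  ))
  invisible(x)
}
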