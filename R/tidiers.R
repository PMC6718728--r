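#' Tidy a nested cross-validation result
#'
#' One row per outer fold: chosen hyperparameters, confusion counts and
#' the fold's balanced error rate.
#'
#' @param x A `myo_cv`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.myo_cv <- function(x, ...) {
  dplyr::mutate(
    x$folds,
    ber = purrr::pmap_dbl(
      list(.data$n_tp, .data$n_fp, .data$n_fn, .data$n_tn),
      function(n_tp, n_fp, n_fn, n_tn) {
        ber(list(n_tp = n_tp, n_fp = n_fp, n_fn = n_fn, n_tn = n_tn))
      }
    )
  )
}

#' Glance at a nested cross-validation result
#'
#' @param x A `myo_cv`.
#' @param ... Unused.
#' @return One-row tibble with pooled confusion counts, BER, AUC and
#'   dataset size.
#' @export
glance.myo_cv <- function(x, ...) {
  tibble(
    n = x$n, n_folds = nrow(x$folds),
    n_tp = x$pooled$n_tp, n_fp = x$pooled$n_fp,
    n_fn = x$pooled$n_fn, n_tn = x$pooled$n_tn,
    ber = x$ber, auc = x$auc
  )
}

#' Tidy a least-squares trend
#'
#' @param x A `myo_trend`.
#' @param ... Unused.
#' @return The per-point diagnostics tibble (`x`, `y`, `fitted`,
#'   `residual`, `cooks_d`).
#' @export
tidy.myo_trend <- function(x, ...) x$diagnostics

#' Glance at a least-squares trend
#'
#' @param x A `myo_trend`.
#' @param ... Unused.
#' @return One-row tibble with `intercept`, `slope`, `max_cooks_d`.
#' @export
glance.myo_trend <- function(x, ...) {
  tibble(
    intercept = x$intercept, slope = x$slope,
    max_cooks_d = max(x$diagnostics$cooks_d)
  )
}

#' Tidy an ANOVA report
#'
#' @param x A `myo_anova`.
#' @param ... Unused.
#' @return The three-way effect table with a `model` column, stacked with
#'   the one-way reduction.
#' @export
tidy.myo_anova <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$three_way, model = "three_way"),
    dplyr::mutate(x$one_way, model = "one_way")
  )
}

#' Tidy a zone failure summary
#'
#' @param x A `myo_zone_summary`.
#' @param ... Unused.
#' @return The per-subject, per-zone mean/sd tibble.
#' @export
tidy.myo_zone_summary <- function(x, ...) x$summary

#' Tidy an experiment report
#'
#' @param x A `myo_experiment`.
#' @param ... Unused.
#' @return The per-set results tibble.
#' @export
tidy.myo_experiment <- function(x, ...) x$results

#' Glance at an experiment report
#'
#' @param x A `myo_experiment`.
#' @param ... Unused.
#' @return One-row tibble with subject count, set count, and the mean BER
#'   over the SC and TC+SC feature sets (the aggregate headline metric).
#' @export
glance.myo_experiment <- function(x, ...) {
  sub <- dplyr::filter(x$results, .data$feature_type %in% c("sc", "tcsc"))
  tibble(
    n_subjects = x$config$n_subjects,
    n_sets = nrow(x$results),
    mean_ber_sc_tcsc = mean(sub$ber),
    mean_auc_sc_tcsc = mean(sub$auc)
  )
}
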