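#' Plot the ROC curve of a nested cross-validation result
#'
#' @param object A `myo_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.myo_cv <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(colour = "#2166ac", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (AUC = %.3f, BER = %.1f%%)", object$auc, object$ber)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a zone failure summary
#'
#' Mean failures per task by zone (bars) and the zone-normalized-time map
#' of mean failure counts (tiles), per subject.
#'
#' @param object A `myo_zone_summary`.
#' @param which `"zones"` for the per-zone bar chart, `"map"` for the
#'   normalized-time histogram.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.myo_zone_summary <- function(object, which = c("zones", "map"), ...) {
  which <- match.arg(which)
  if (which == "zones") {
    d <- dplyr::filter(object$summary, .data$zone != "OVERALL")
    ggplot2::ggplot(d, ggplot2::aes(x = .data$zone, y = .data$mean, fill = .data$zone)) +
      ggplot2::geom_col() +
      ggplot2::geom_errorbar(
        ggplot2::aes(
          ymin = pmax(.data$mean - .data$sd, 0),
          ymax = .data$mean + .data$sd
        ),
        width = 0.2
      ) +
      ggplot2::facet_wrap(~subject) +
      ggplot2::labs(
        x = NULL, y = "Mean failures per task",
        title = "Failures by task zone"
      ) +
      ggplot2::guides(fill = "none") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(
      object$histogram,
      ggplot2::aes(x = .data$bin, y = .data$subject, fill = .data$mean_count)
    ) +
      ggplot2::geom_tile() +
      ggplot2::facet_grid(~zone) +
      ggplot2::scale_fill_viridis_c(name = "Mean failures") +
      ggplot2::labs(
        x = "Zone-normalized time bin", y = NULL,
        title = "Temporal map of failures (zone-normalized time)"
      ) +
      ggplot2::theme_minimal()
  }
}

#' Plot experiment BER by feature type
#'
#' @param object A `myo_experiment`.
#' @param ... Unused.
#' @return A ggplot (boxplot of BER grouped by feature type).
#' @export
autoplot.myo_experiment <- function(object, ...) {
  ggplot2::ggplot(
    object$results,
    ggplot2::aes(x = .data$feature_type, y = .data$ber, fill = .data$feature_type)
  ) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(
      x = "Feature type", y = "Balanced error rate (%)",
      title = "Detector BER by feature type"
    ) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Plot a session excerpt
#'
#' Prediction channels with the actuation threshold, task zone shading and
#' ground-truth failure/button instants, over a time range.
#'
#' @param session A `myo_session`.
#' @param from,to Time range in seconds (defaults to the first task).
#' @param threshold Actuation threshold to draw.
#' @return A ggplot.
#' @export
plot_session <- function(session, from = NULL, to = NULL, threshold = 0.3) {
  from <- from %||% session$tasks$t_start[1]
  to <- to %||% session$tasks$t_end[1]
  pred <- dplyr::filter(session$prediction, .data$time >= from, .data$time <= to)
  long <- tidyr::pivot_longer(pred, -"time",
    names_to = "channel", values_to = "prediction"
  )
  fails <- dplyr::filter(session$failures, .data$time >= from, .data$time <= to)
  btns <- dplyr::filter(session$buttons, .data$time >= from, .data$time <= to)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$prediction)) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$channel), linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "Time (s)", y = "Myocontrol prediction") +
    ggplot2::theme_minimal()
  if (nrow(fails)) {
    p <- p + ggplot2::geom_vline(
      data = fails, ggplot2::aes(xintercept = .data$time),
      colour = "red", alpha = 0.6
    )
  }
  if (nrow(btns)) {
    p <- p + ggplot2::geom_point(
      data = dplyr::mutate(btns, y = 1),
      ggplot2::aes(x = .data$time, y = .data$y),
      shape = 17, colour = "blue", size = 2
    )
  }
  p
}
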