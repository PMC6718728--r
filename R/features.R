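#' Binarize the digit-status trace
#'
#' Collapses the six-motor status trace onto the four myocontrol channels
#' and onto two motion classes: `flexing` (1, replacing closing/closed) and
#' `extending` (0, replacing opening/open). A `STALLED` sample holds the
#' previous binary value (a stall preserves the last motion direction); a
#' leading stall maps to 0. The mechanically coupled middle/ring/little
#' digits are represented by the middle digit, so channels are thumb
#' flexion, index, middle group and thumb abduction — the same four
#' channels as the prediction trace.
#'
#' @param digit_status Digit-status tibble (`time`, `d1`..`d6`).
#' @return Tibble with columns `time`, `s1`..`s4`, values in \{0, 1\}.
#' @export
filter_digit_status <- function(digit_status) {
  out <- tibble(time = digit_status$time)
  for (ch in 1:4) {
    s <- toupper(digit_status[[paste0("d", CHANNEL_DIGITS[ch])]])
    bad <- which(!s %in% DIGIT_STATUSES)
    if (length(bad)) {
      abort(sprintf("unknown digit status '%s' at row %d", s[bad[1]], bad[1]))
    }
    v <- ifelse(s %in% c("CLOSING", "CLOSED"), 1L,
      ifelse(s %in% c("OPENING", "OPEN"), 0L, NA_integer_)
    )
    # hold-last fill for STALLED; leading stall -> 0
    idx <- cummax(ifelse(is.na(v), 0L, seq_along(v)))
    out[[paste0("s", ch)]] <- ifelse(idx == 0L, 0L, v[pmax(idx, 1L)])
  }
  out
}

#' Count threshold crossings per channel
#'
#' Number of times each prediction channel crosses the actuation threshold
#' within a window, in either direction: sign changes of `x - threshold`
#' across consecutive samples. Samples exactly at the threshold count as
#' below it.
#'
#' @param window Prediction samples of one window: a matrix or data frame
#'   whose numeric columns are the channels (a `p1`..`p4` tibble works).
#' @param threshold Actuation threshold in (0, 1).
#' @return Integer vector of per-channel counts.
#' @examples
#' count_threshold_crossings(cbind(c(0.1, 0.9, 0.1)), 0.3)
#' @export
count_threshold_crossings <- function(window, threshold = 0.3) {
  x <- as_channel_matrix(window, "p")
  if (nrow(x) == 0) abort("empty window")
  if (threshold <= 0 || threshold >= 1) abort("threshold must lie in (0, 1)")
  if (nrow(x) == 1) {
    return(integer(ncol(x)))
  }
  above <- x > threshold
  as.integer(colSums(above[-1, , drop = FALSE] != above[-nrow(x), , drop = FALSE]))
}

#' Count status changes per channel
#'
#' Number of transitions of the binarized (flexing/extending) digit-status
#' signal within a window: samples whose value differs from their
#' predecessor.
#'
#' @param window Filtered-status samples of one window: matrix or data
#'   frame whose numeric columns are the channels (an `s1`..`s4` tibble
#'   works).
#' @return Integer vector of per-channel counts.
#' @examples
#' count_status_changes(cbind(c(0, 0, 1, 1, 0)))
#' @export
count_status_changes <- function(window) {
  x <- as_channel_matrix(window, "s")
  if (nrow(x) == 0) abort("empty window")
  if (nrow(x) == 1) {
    return(integer(ncol(x)))
  }
  as.integer(colSums(x[-1, , drop = FALSE] != x[-nrow(x), , drop = FALSE]))
}

as_channel_matrix <- function(window, prefix) {
  if (is.data.frame(window)) {
    cols <- grep(paste0("^", prefix, "[0-9]+$"), names(window), value = TRUE)
    if (!length(cols)) cols <- names(window)[vapply(window, is.numeric, logical(1))]
    cols <- setdiff(cols, "time")
    window <- as.matrix(window[cols])
  }
  as.matrix(window)
}

#' Enumerate sliding windows over a task span
#'
#' Tiles half-open windows `[start, start + length)` from `t_start` with a
#' step equal to the window length (no overlap) or half of it. A trailing
#' partial window is dropped so counts stay comparable across window sizes;
#' windows never span task boundaries.
#'
#' @param t_start,t_end Task span in seconds.
#' @param length Window length in seconds (the study used 0.5, 1 and 3 s).
#' @param overlap `"none"` or `"half"`.
#' @return Tibble with columns `start`, `end`; zero rows if the span is
#'   shorter than one window.
#' @examples
#' make_windows(0, 10, 1, "half")
#' @export
make_windows <- function(t_start, t_end, length, overlap = c("none", "half")) {
  overlap <- match.arg(overlap)
  if (length <= 0) abort("window length must be positive")
  step <- if (overlap == "half") length / 2 else length
  span <- t_end - t_start
  if (span < length - 1e-9) {
    return(tibble(start = numeric(), end = numeric()))
  }
  k <- floor((span - length) / step + 1e-9)
  starts <- t_start + (0:k) * step
  tibble(start = starts, end = starts + length)
}

#' Label a window from the ground-truth failure instants
#'
#' A window is a failure window (1) iff at least one failure instant falls
#' inside its half-open span `[start, end)`; otherwise it is a success
#' window (0). A failure exactly at the end boundary belongs to the next
#' window.
#'
#' @param start,end Window span in seconds.
#' @param failure_times Numeric vector of failure instants.
#' @return Integer 0 or 1.
#' @export
label_window <- function(start, end, failure_times) {
  as.integer(any(failure_times >= start & failure_times < end))
}

#' Extract a labeled feature dataset from a session
#'
#' Slides windows over each task (restarting at every `t_start`) and
#' computes the per-window count features: `tc` (threshold crossings of the
#' four prediction channels), `sc` (status changes of the four binarized
#' digit-status channels) or `tcsc` (their concatenation, dimension 8).
#' Windows are labeled 1 when they contain a ground-truth failure instant.
#' Three feature types, three window lengths and two overlaps give the
#' eighteen canonical feature sets per subject.
#'
#' @param session A `myo_session`.
#' @param window_length Window length in seconds.
#' @param overlap `"none"` or `"half"`.
#' @param feature_type `"tc"`, `"sc"` or `"tcsc"`.
#' @param threshold Actuation threshold used for the TC counts.
#' @return Tibble with columns `task`, `window_start`, `window_end`, the
#'   count columns (`tc1`..`tc4` and/or `sc1`..`sc4`) and `label`.
#' @examples
#' s <- generate_session(sim_config(seed = 3, n_tasks = 2))
#' extract_dataset(s, 3, "none", "tcsc")
#' @export
extract_dataset <- function(session, window_length, overlap = c("none", "half"),
                            feature_type = c("tc", "sc", "tcsc"),
                            threshold = 0.3) {
  overlap <- match.arg(overlap)
  feature_type <- match.arg(feature_type)
  time <- session$prediction$time
  pred <- as.matrix(session$prediction[paste0("p", 1:4)])
  need_sc <- feature_type %in% c("sc", "tcsc")
  need_tc <- feature_type %in% c("tc", "tcsc")
  if (need_sc) {
    filt <- as.matrix(filter_digit_status(session$digit_status)[paste0("s", 1:4)])
  }
  rows <- list()
  for (k in seq_len(nrow(session$tasks))) {
    win <- make_windows(
      session$tasks$t_start[k], session$tasks$t_end[k],
      window_length, overlap
    )
    if (!nrow(win)) next
    for (w in seq_len(nrow(win))) {
      i1 <- findInterval(win$start[w] - 1e-9, time) + 1L
      i2 <- findInterval(win$end[w] - 1e-9, time)
      if (i2 < i1) next
      idx <- i1:i2
      counts <- c(
        if (need_tc) count_threshold_crossings(pred[idx, , drop = FALSE], threshold),
        if (need_sc) count_status_changes(filt[idx, , drop = FALSE])
      )
      rows[[length(rows) + 1]] <- c(
        task = k, window_start = win$start[w], window_end = win$end[w],
        counts,
        label = label_window(win$start[w], win$end[w], session$failures$time)
      )
    }
  }
  cnames <- c(
    if (need_tc) paste0("tc", 1:4),
    if (need_sc) paste0("sc", 1:4)
  )
  if (!length(rows)) {
    out <- as_tibble(stats::setNames(
      rep(list(numeric()), 4 + length(cnames)),
      c("task", "window_start", "window_end", cnames, "label")
    ))
    out$task <- integer()
    out$label <- integer()
    return(out)
  }
  m <- do.call(rbind, rows)
  colnames(m) <- c("task", "window_start", "window_end", cnames, "label")
  out <- as_tibble(as.data.frame(m))
  out$task <- as.integer(out$task)
  out$label <- as.integer(out$label)
  for (cn in cnames) out[[cn]] <- as.integer(out[[cn]])
  out
}
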