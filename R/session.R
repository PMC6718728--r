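#' Digit status vocabulary
#'
#' The five per-motor feedback flags reported by the prosthetic hand.
#'
#' @format Character vector of length five.
#' @export
DIGIT_STATUSES <- c("OPENING", "OPEN", "CLOSING", "CLOSED", "STALLED")

#' Task zone names
#'
#' Each carrying task splits into three zones delimited by the intent
#' timeline: Pre-Grasp (rest), Grasp (power grasp) and Post-Grasp (rest).
#'
#' @format Character vector of length three.
#' @export
TASK_ZONES <- c("PRE_GRASP", "GRASP", "POST_GRASP")

# Mapping of the six hand motors onto the four myocontrol channels:
# thumb flexion, index, middle (representative of the mechanically coupled
# middle/ring/little group) and thumb abduction.
DIGIT_CHANNEL_MAP <- c(1L, 2L, 3L, 3L, 3L, 4L)
CHANNEL_DIGITS <- c(1L, 2L, 3L, 6L)

#' Create a task timeline
#'
#' A timeline pins the four intent instants of one grasp-carry-release task:
#' the subject rests from `t_start`, grasps at `t_grasp`, releases at
#' `t_release` and rests again until `t_end`. All times are session-absolute
#' seconds.
#'
#' @param t_start,t_grasp,t_release,t_end Instants in seconds, strictly
#'   increasing.
#' @return A one-row tibble with columns `t_start`, `t_grasp`, `t_release`,
#'   `t_end`.
#' @examples
#' task_timeline(0, 5, 12, 20)
#' @export
task_timeline <- function(t_start, t_grasp, t_release, t_end) {
  tl <- tibble(
    t_start = as.numeric(t_start), t_grasp = as.numeric(t_grasp),
    t_release = as.numeric(t_release), t_end = as.numeric(t_end)
  )
  validate_timelines(tl)
  tl
}

validate_timelines <- function(tasks) {
  stopifnot(is.data.frame(tasks))
  req <- c("t_start", "t_grasp", "t_release", "t_end")
  if (!all(req %in% names(tasks))) {
    abort("task timeline needs columns t_start, t_grasp, t_release, t_end")
  }
  ok <- tasks$t_start < tasks$t_grasp & tasks$t_grasp < tasks$t_release &
    tasks$t_release < tasks$t_end
  if (!all(ok)) {
    abort(sprintf(
      "non-monotone task timeline in row(s) %s: need t_start < t_grasp < t_release < t_end",
      paste(which(!ok), collapse = ", ")
    ))
  }
  if (nrow(tasks) > 1) {
    gap_ok <- tasks$t_start[-1] >= tasks$t_end[-nrow(tasks)]
    if (!all(gap_ok)) abort("tasks must be ordered and non-overlapping")
  }
  invisible(tasks)
}

#' Construct a myocontrol session
#'
#' Bundles the synchronized traces of one recording session: a four-channel
#' myocontrol prediction trace in \[0, 1\], the six-motor digit-status trace,
#' the task timelines, the ground-truth failure events and the subject's
#' button presses. All invariants are checked on construction.
#'
#' @param prediction Tibble with columns `time`, `p1`..`p4`; predictions in
#'   \[0, 1\], uniformly sampled.
#' @param digit_status Tibble with columns `time`, `d1`..`d6`; statuses from
#'   [DIGIT_STATUSES] (case-insensitive), same timebase as `prediction`.
#' @param tasks Tibble of task timelines (see [task_timeline()]).
#' @param failures Tibble with columns `time`, `channel` (1-4) and `kind`
#'   (`"SPURIOUS_CLOSE"` or `"SPURIOUS_OPEN"`); may have zero rows.
#' @param buttons Tibble with a `time` column; may have zero rows.
#' @param subject_id Character scalar.
#' @param sample_rate Sampling rate of both traces, in Hz.
#' @return An object of class `myo_session`.
#' @export
myo_session <- function(prediction, digit_status, tasks,
                        failures = NULL, buttons = NULL,
                        subject_id = "S1", sample_rate = 100) {
  failures <- failures %||%
    tibble(time = numeric(), channel = integer(), kind = character())
  buttons <- buttons %||% tibble(time = numeric())
  session <- structure(
    list(
      prediction = as_tibble(prediction),
      digit_status = as_tibble(digit_status),
      tasks = as_tibble(tasks),
      failures = as_tibble(failures),
      buttons = as_tibble(buttons),
      subject_id = as.character(subject_id),
      sample_rate = as.numeric(sample_rate)
    ),
    class = "myo_session"
  )
  validate_session(session)
}

#' Validate a session object
#'
#' Checks every structural invariant: prediction range, status vocabulary,
#' shared timebase, timeline monotonicity, task ordering, and that events
#' fall inside the session span. Status strings are normalized to uppercase.
#'
#' @param session A `myo_session`.
#' @return The (normalized) session, invisibly classed as `myo_session`.
#' @export
validate_session <- function(session) {
  pred <- session$prediction
  stat <- session$digit_status
  pcols <- paste0("p", 1:4)
  dcols <- paste0("d", 1:6)
  if (!all(c("time", pcols) %in% names(pred))) {
    abort("prediction trace needs columns time, p1..p4")
  }
  if (!all(c("time", dcols) %in% names(stat))) {
    abort("digit status trace needs columns time, d1..d6")
  }
  if (nrow(pred) != nrow(stat) || any(abs(pred$time - stat$time) > 1e-9)) {
    abort("prediction and digit status traces must share one timebase")
  }
  for (j in seq_along(pcols)) {
    x <- pred[[pcols[j]]]
    bad <- which(x < 0 | x > 1 | !is.finite(x))
    if (length(bad)) {
      abort(sprintf(
        "prediction value %.4g out of [0, 1] on channel %d at t = %.4f s",
        x[bad[1]], j, pred$time[bad[1]]
      ))
    }
  }
  for (j in seq_along(dcols)) {
    s <- toupper(as.character(stat[[dcols[j]]]))
    bad <- which(!s %in% DIGIT_STATUSES)
    if (length(bad)) {
      abort(sprintf(
        "unknown digit status '%s' in column %s, row %d",
        stat[[dcols[j]]][bad[1]], dcols[j], bad[1]
      ))
    }
    stat[[dcols[j]]] <- s
  }
  session$digit_status <- stat
  validate_timelines(session$tasks)
  span <- range(pred$time)
  if (nrow(session$tasks) &&
      (min(session$tasks$t_start) < span[1] - 1e-9 ||
       max(session$tasks$t_end) > span[2] + 1e-9)) {
    abort("traces must cover the union of task spans")
  }
  for (nm in c("failures", "buttons")) {
    tt <- session[[nm]]$time
    if (length(tt) && (any(tt < span[1] - 1e-9) || any(tt > span[2] + 1e-9))) {
      abort(sprintf("%s events must lie within the session span", nm))
    }
  }
  invisible(structure(session, class = "myo_session"))
}

#' @export
print.myo_session <- function(x, ...) {
  cat(sprintf(
    "<myo_session> subject %s: %d samples @ %g Hz, %d tasks, %d failures, %d button presses\n",
    x$subject_id, nrow(x$prediction), x$sample_rate,
    nrow(x$tasks), nrow(x$failures), nrow(x$buttons)
  ))
  invisible(x)
}

#' Task zone of an instant
#'
#' Maps an instant to its zone within a task: `PRE_GRASP` on
#' \[t_start, t_grasp), `GRASP` on \[t_grasp, t_release) and `POST_GRASP` on
#' \[t_release, t_end\]. Half-open boundaries make the partition exact: the
#' grasp instant itself belongs to the Grasp zone.
#'
#' @param t Numeric vector of instants in seconds.
#' @param timeline A one-row timeline (see [task_timeline()]).
#' @return Character vector over [TASK_ZONES].
#' @examples
#' tl <- task_timeline(0, 5, 12, 20)
#' zone_of(c(0, 5, 12, 20), tl)
#' @export
zone_of <- function(t, timeline) {
  stopifnot(nrow(timeline) == 1)
  if (any(t < timeline$t_start | t > timeline$t_end)) {
    abort("t outside the task's [t_start, t_end]")
  }
  ifelse(t < timeline$t_grasp, "PRE_GRASP",
    ifelse(t < timeline$t_release, "GRASP", "POST_GRASP")
  )
}

# Task (row index) enclosing each instant; NA if between tasks.
task_index_of <- function(t, tasks) {
  vapply(t, function(ti) {
    i <- which(tasks$t_start - 1e-9 <= ti & ti <= tasks$t_end + 1e-9)
    if (length(i)) i[1] else NA_integer_
  }, integer(1))
}

#' Write a session to disk
#'
#' Serializes a session into a directory holding two plain-text files:
#' `traces.csv` (columns `time,p1..p4,d1..d6`, statuses as uppercase
#' strings) and `session.json` (subject id, sample rate, tasks, failures,
#' buttons). Numbers are written at full precision so that
#' [read_session()] reproduces the session exactly.
#'
#' @param session A `myo_session`.
#' @param path Directory to write into (created if missing).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create session directory '%s'", path))
  }
  traces <- dplyr::bind_cols(
    session$prediction,
    dplyr::select(session$digit_status, -"time")
  )
  # format doubles at 17 significant digits so re-reading is bit-exact
  traces <- dplyr::mutate(traces, dplyr::across(
    dplyr::where(is.double), ~ sprintf("%.17g", .x)
  ))
  readr::write_csv(traces, file.path(path, "traces.csv"), progress = FALSE)
  meta <- list(
    subject_id = session$subject_id,
    sample_rate = session$sample_rate,
    tasks = session$tasks,
    failures = session$failures,
    buttons = session$buttons
  )
  jsonlite::write_json(meta, file.path(path, "session.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = I(17), null = "list"
  )
  invisible(path)
}

#' Read a session from disk
#'
#' Counterpart of [write_session()]. All type invariants are re-checked on
#' load; case-insensitive status strings are normalized to uppercase.
#'
#' @param path Directory holding `traces.csv` and `session.json`.
#' @return A validated `myo_session`.
#' @export
read_session <- function(path) {
  tf <- file.path(path, "traces.csv")
  mf <- file.path(path, "session.json")
  if (!file.exists(tf) || !file.exists(mf)) {
    abort(sprintf("session files not found under '%s'", path))
  }
  # base strtod parses doubles with correct rounding, keeping the
  # write -> read cycle bit-exact
  traces <- as_tibble(utils::read.csv(
    tf,
    colClasses = c(rep("numeric", 5), rep("character", 6))
  ))
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  as_events <- function(x, cols) {
    if (is.null(x) || length(x) == 0 || all(lengths(x) == 0)) {
      out <- lapply(cols, function(cl) if (cl == "kind") character() else numeric())
      names(out) <- cols
      return(as_tibble(out))
    }
    as_tibble(x)[cols]
  }
  failures <- as_events(meta$failures, c("time", "channel", "kind"))
  if (nrow(failures)) failures$channel <- as.integer(failures$channel)
  myo_session(
    prediction = traces[c("time", paste0("p", 1:4))],
    digit_status = traces[c("time", paste0("d", 1:6))],
    tasks = as_tibble(meta$tasks),
    failures = failures,
    buttons = as_events(meta$buttons, "time"),
    subject_id = meta$subject_id,
    sample_rate = meta$sample_rate
  )
}
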