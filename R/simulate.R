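#' Simulator configuration
#'
#' Parameters of the synthetic session generator. Defaults emulate the
#' grasp-carry-release study conditions: 20 tasks per session, a 0.3
#' actuation threshold, a Post-Grasp zone that is on average the longest,
#' per-zone instability intensities in a 1 : 1 : 2.5 Pre : Grasp : Post
#' ratio totalling about three failures per task, and button reporting that
#' is delayed, refractory and occasionally absent.
#'
#' @param seed Integer seed; a session is a deterministic function of its
#'   configuration.
#' @param n_tasks Number of carrying tasks in the session.
#' @param sample_rate Sampling rate of the generated traces, Hz.
#' @param zone_duration_means Named numeric: mean duration (s) of the
#'   `pre_grasp`, `grasp` and `post_grasp` zones; Post-Grasp longest.
#' @param zone_duration_sd,zone_duration_min Spread and lower truncation (s)
#'   of the per-task zone durations.
#' @param task_gap Seated pause between consecutive tasks, s.
#' @param failure_intensity Named numeric: expected instability events per
#'   task in each zone (Poisson).
#' @param oscillation_amplitude,oscillation_freq Peak excursion (prediction
#'   units) and frequency (Hz) of the oscillatory transient injected at each
#'   failure.
#' @param burst_duration Duration (s) of one injected transient.
#' @param actuation_threshold Prediction level above which the hand is
#'   driven proportionally; below it the hand returns to the all-open home
#'   configuration.
#' @param digit_speed Full-travel digit speed, fraction of travel per second.
#' @param stall_during_grasp If `TRUE`, digits meet object contact during
#'   the Grasp zone and report `STALLED`.
#' @param contact_position Digit closure fraction at which contact blocks
#'   further closing.
#' @param rest_level,grasp_level Prediction baselines for the rest and
#'   power-grasp intents.
#' @param noise_sd Standard deviation of the band-limited (AR(1)) prediction
#'   noise.
#' @param noise_ar AR(1) coefficient of the noise at the sample rate.
#' @param ramp_duration Raised-cosine transition time (s) between intent
#'   levels.
#' @param settle_window Time (s) after an intent switch during which
#'   threshold crossings count as transitional rather than contrary.
#' @param button_delay_mean,button_delay_sd Normal (truncated at zero)
#'   cognitive delay (s) between a noticed failure and the button press.
#' @param button_miss_prob Probability that a failure goes unnoticed.
#' @param button_refractory Time (s) after a press during which further
#'   failures are not signalled.
#' @return A list of class `myo_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_tasks = 20L,
                       sample_rate = 100,
                       zone_duration_means = c(pre_grasp = 6, grasp = 8, post_grasp = 12),
                       zone_duration_sd = 1,
                       zone_duration_min = 2,
                       task_gap = 2,
                       failure_intensity = c(pre_grasp = 0.65, grasp = 0.65, post_grasp = 1.7),
                       oscillation_amplitude = 0.55,
                       oscillation_freq = 3,
                       burst_duration = 1.2,
                       actuation_threshold = 0.3,
                       digit_speed = 1.2,
                       stall_during_grasp = TRUE,
                       contact_position = 0.6,
                       rest_level = 0.05,
                       grasp_level = 0.7,
                       noise_sd = 0.02,
                       noise_ar = 0.95,
                       ramp_duration = 0.3,
                       settle_window = 0.5,
                       button_delay_mean = 1.5,
                       button_delay_sd = 0.7,
                       button_miss_prob = 0.15,
                       button_refractory = 3) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "myo_sim_config")
}

validate_sim_config <- function(cfg) {
  zones <- c("pre_grasp", "grasp", "post_grasp")
  if (!all(zones %in% names(cfg$zone_duration_means)) ||
      !all(zones %in% names(cfg$failure_intensity))) {
    abort("zone_duration_means and failure_intensity need names pre_grasp, grasp, post_grasp")
  }
  if (any(cfg$zone_duration_means <= 0) || cfg$zone_duration_min <= 0) {
    abort("zone durations must be positive")
  }
  if (any(cfg$failure_intensity < 0)) abort("failure intensities must be >= 0")
  if (cfg$actuation_threshold <= 0 || cfg$actuation_threshold >= 1) {
    abort("actuation_threshold must lie in (0, 1)")
  }
  if (cfg$button_miss_prob < 0 || cfg$button_miss_prob > 1) {
    abort("button_miss_prob must lie in [0, 1]")
  }
  if (cfg$n_tasks < 1 || cfg$sample_rate <= 0) {
    abort("need at least one task and a positive sample rate")
  }
  invisible(cfg)
}

# Raised-cosine step from 0 to 1 over [0, dur].
ramp01 <- function(t, dur) {
  u <- pmin(pmax(t / dur, 0), 1)
  0.5 * (1 - cos(pi * u))
}

#' Generate a synthetic myocontrol session
#'
#' Produces one subject-session with known ground truth. Each task scripts
#' the intent sequence rest / power-grasp / rest; the grasp-driven
#' prediction channels follow the intent through raised-cosine transitions
#' plus band-limited noise that is kept clear of the actuation threshold
#' except during injected instability events. Failure counts per zone are
#' Poisson with the configured intensities; each failure injects a windowed
#' oscillatory transient that drives one channel across the threshold
#' contrary to intent (a spurious close during rest, a spurious open during
#' grasp), and the recorded failure time is the first sample of that
#' contrary crossing. Digit statuses come from [simulate_hand()], button
#' presses from [simulate_buttons()].
#'
#' @param cfg A [sim_config()].
#' @param subject_id Subject label stored in the session.
#' @return A validated `myo_session`.
#' @examples
#' s <- generate_session(sim_config(seed = 42, n_tasks = 2))
#' s
#' @export
generate_session <- function(cfg = sim_config(), subject_id = "S1") {
  validate_sim_config(cfg)
  withr::with_seed(cfg$seed, generate_session_impl(cfg, subject_id))
}

generate_session_impl <- function(cfg, subject_id) {
  rate <- cfg$sample_rate
  thr <- cfg$actuation_threshold
  zones <- c("pre_grasp", "grasp", "post_grasp")

  # -- task timelines ---------------------------------------------------
  dur <- matrix(0, cfg$n_tasks, 3, dimnames = list(NULL, zones))
  for (z in 1:3) {
    dur[, z] <- pmax(
      rnorm(cfg$n_tasks, cfg$zone_duration_means[zones[z]], cfg$zone_duration_sd),
      cfg$zone_duration_min
    )
  }
  cursor <- cfg$task_gap
  tasks <- vector("list", cfg$n_tasks)
  for (k in seq_len(cfg$n_tasks)) {
    t_start <- cursor
    t_grasp <- t_start + dur[k, 1]
    t_release <- t_grasp + dur[k, 2]
    t_end <- t_release + dur[k, 3]
    tasks[[k]] <- tibble(
      t_start = unname(t_start), t_grasp = unname(t_grasp),
      t_release = unname(t_release), t_end = unname(t_end)
    )
    cursor <- t_end + cfg$task_gap
  }
  tasks <- dplyr::bind_rows(tasks)
  n <- round(cursor * rate) + 1L
  time <- (seq_len(n) - 1L) / rate

  # -- intent baseline with raised-cosine transitions -------------------
  grasp_env <- numeric(n) # 0 = rest, 1 = power grasp, on channels 1..3
  for (k in seq_len(nrow(tasks))) {
    i <- which(time >= tasks$t_grasp[k] & time < tasks$t_release[k] + cfg$ramp_duration)
    grasp_env[i] <- ramp01(time[i] - tasks$t_grasp[k], cfg$ramp_duration) -
      ramp01(time[i] - tasks$t_release[k], cfg$ramp_duration)
  }
  base_grasp <- cfg$rest_level + (cfg$grasp_level - cfg$rest_level) * grasp_env
  pred <- matrix(0, n, 4)
  innov_sd <- cfg$noise_sd * sqrt(1 - cfg$noise_ar^2)
  for (ch in 1:4) {
    noise <- as.numeric(stats::filter(rnorm(n, 0, innov_sd), cfg$noise_ar,
      method = "recursive"
    ))
    pred[, ch] <- (if (ch <= 3) base_grasp else cfg$rest_level) + noise
  }

  # -- draw failures and inject oscillatory transients ------------------
  events <- draw_failure_times(tasks, cfg)
  events <- assign_failure_channels(events, cfg)
  burst_mask <- matrix(FALSE, n, 4)
  if (nrow(events)) {
    for (e in seq_len(nrow(events))) {
      i <- which(time >= events$t0[e] & time <= events$t0[e] + cfg$burst_duration)
      u <- time[i] - events$t0[e]
      shape <- 0.5 * (1 - cos(2 * pi * u / cfg$burst_duration)) *
        sin(2 * pi * cfg$oscillation_freq * u)
      if (max(shape) <= 0) next
      # unit-peak waveform: the amplitude is the guaranteed peak excursion
      delta <- cfg$oscillation_amplitude * shape / max(shape)
      sgn <- if (events$kind[e] == "SPURIOUS_CLOSE") 1 else -1
      pred[i, events$channel[e]] <- pred[i, events$channel[e]] + sgn * delta
      burst_mask[i, events$channel[e]] <- TRUE
    }
  }

  # -- clamp the signal clear of the threshold outside bursts/settling --
  grasp_intent <- rep(FALSE, n)
  settle <- rep(FALSE, n)
  for (k in seq_len(nrow(tasks))) {
    grasp_intent[time >= tasks$t_grasp[k] & time < tasks$t_release[k]] <- TRUE
    settle[(time >= tasks$t_grasp[k] & time < tasks$t_grasp[k] + cfg$settle_window) |
      (time >= tasks$t_release[k] & time < tasks$t_release[k] + cfg$settle_window)] <- TRUE
  }
  margin <- 0.03
  for (ch in 1:4) {
    ig <- if (ch <= 3) grasp_intent else rep(FALSE, n)
    sett <- if (ch <= 3) settle else rep(FALSE, n)
    lo <- !ig & !sett & !burst_mask[, ch]
    hi <- ig & !sett & !burst_mask[, ch]
    pred[lo, ch] <- pmin(pred[lo, ch], thr - margin)
    pred[hi, ch] <- pmax(pred[hi, ch], thr + margin)
  }
  pred <- pmin(pmax(pred, 0), 1)

  # -- ground-truth failure times: first contrary crossing of each burst -
  failures <- locate_burst_crossings(events, pred, time, thr, cfg)

  prediction <- tibble(
    time = time,
    p1 = pred[, 1], p2 = pred[, 2], p3 = pred[, 3], p4 = pred[, 4]
  )

  # -- hand, buttons ----------------------------------------------------
  contact <- if (cfg$stall_during_grasp) {
    tidyr::expand_grid(task = seq_len(nrow(tasks)), digit = 1:5) |>
      dplyr::mutate(
        start = tasks$t_grasp[.data$task],
        end = tasks$t_release[.data$task],
        position = cfg$contact_position
      ) |>
      dplyr::select("digit", "start", "end", "position")
  } else {
    tibble(digit = integer(), start = numeric(), end = numeric(), position = numeric())
  }
  digit_status <- simulate_hand(prediction, contact, cfg)
  buttons <- simulate_buttons(failures, cfg)

  myo_session(
    prediction = prediction, digit_status = digit_status, tasks = tasks,
    failures = failures, buttons = buttons,
    subject_id = subject_id, sample_rate = rate
  )
}

# Poisson number of failures per task and zone; placement uniform in the
# Pre-Grasp and Grasp zones and mid-zone concentrated (Beta(2, 2)) in
# Post-Grasp, always clear of zone edges so the whole transient fits inside
# the zone and outside the post-switch settle window.
draw_failure_times <- function(tasks, cfg) {
  zones <- c("pre_grasp", "grasp", "post_grasp")
  out <- list()
  for (k in seq_len(nrow(tasks))) {
    bounds <- c(
      tasks$t_start[k], tasks$t_grasp[k],
      tasks$t_release[k], tasks$t_end[k]
    )
    for (z in 1:3) {
      lam <- cfg$failure_intensity[zones[z]]
      if (lam <= 0) next
      n_ev <- rpois(1, lam)
      if (n_ev == 0) next
      lo <- bounds[z] + cfg$settle_window
      hi <- bounds[z + 1] - cfg$burst_duration - 0.05
      if (hi <= lo) next
      u <- if (z == 3) rbeta(n_ev, 2, 2) else runif(n_ev)
      out[[length(out) + 1]] <- tibble(
        task = k, zone = zones[z],
        t0 = lo + u * (hi - lo),
        kind = if (z == 2) "SPURIOUS_OPEN" else "SPURIOUS_CLOSE"
      )
    }
  }
  if (!length(out)) {
    return(tibble(
      task = integer(), zone = character(), t0 = numeric(),
      kind = character(), channel = integer()
    ))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$t0)
}

# Spurious closes may hit any of the four channels, spurious opens only the
# grasp-driven ones (1..3). Temporally overlapping transients are pushed to
# distinct channels so each keeps its own contrary crossing.
assign_failure_channels <- function(events, cfg) {
  ch <- integer(nrow(events))
  keep <- logical(nrow(events))
  for (e in seq_len(nrow(events))) {
    allowed <- if (events$kind[e] == "SPURIOUS_OPEN") 1:3 else 1:4
    prev <- which(keep & events$t0 > events$t0[e] - cfg$burst_duration &
      seq_len(nrow(events)) < e)
    free <- setdiff(allowed, ch[prev])
    if (!length(free)) next
    ch[e] <- free[sample.int(length(free), 1)]
    keep[e] <- TRUE
  }
  events$channel <- ch
  events[keep, , drop = FALSE]
}

locate_burst_crossings <- function(events, pred, time, thr, cfg) {
  if (!nrow(events)) {
    return(tibble(time = numeric(), channel = integer(), kind = character()))
  }
  res <- list()
  for (e in seq_len(nrow(events))) {
    i <- which(time >= events$t0[e] & time <= events$t0[e] + cfg$burst_duration)
    if (length(i) < 2) next
    s <- pred[i, events$channel[e]] > thr
    hit <- if (events$kind[e] == "SPURIOUS_CLOSE") {
      which(s[-1] & !s[-length(s)])
    } else {
      which(!s[-1] & s[-length(s)])
    }
    if (!length(hit)) next
    res[[length(res) + 1]] <- tibble(
      time = time[i[hit[1] + 1]],
      channel = as.integer(events$channel[e]),
      kind = events$kind[e]
    )
  }
  if (!length(res)) {
    return(tibble(time = numeric(), channel = integer(), kind = character()))
  }
  dplyr::arrange(dplyr::bind_rows(res), .data$time)
}

#' Simulate the prosthetic hand electromechanics
#'
#' Integrates the six digit positions under the threshold-triggered
#' proportional control law: below the actuation threshold a digit is
#' driven toward the all-open home configuration at full speed; above it,
#' it closes at a speed proportional to the prediction excess over the
#' threshold. The coupled middle/ring/little digits share the third
#' prediction channel and the thumb abduction motor the fourth. Per-sample
#' statuses are `CLOSING`/`OPENING` while moving, `OPEN`/`CLOSED` at the
#' travel limits, and `STALLED` when commanded to close against contact.
#'
#' @param prediction Prediction trace tibble (`time`, `p1`..`p4`).
#' @param contact Contact schedule: tibble with columns `digit`, `start`,
#'   `end`, `position` (closure fraction at which the digit blocks). Zero
#'   rows mean free motion.
#' @param cfg A [sim_config()] (threshold and digit speed are used).
#' @return Digit-status tibble (`time`, `d1`..`d6`).
#' @export
simulate_hand <- function(prediction, contact, cfg = sim_config()) {
  time <- prediction$time
  n <- length(time)
  if (n < 2) abort("prediction trace too short to simulate")
  pred <- as.matrix(prediction[paste0("p", 1:4)])
  if (any(!is.finite(pred))) abort("prediction trace contains non-finite values")
  dt <- time[2] - time[1]
  thr <- cfg$actuation_threshold
  speed <- cfg$digit_speed

  cap <- matrix(1, n, 6)
  if (nrow(contact)) {
    for (r in seq_len(nrow(contact))) {
      i <- which(time >= contact$start[r] & time < contact$end[r])
      cap[i, contact$digit[r]] <- pmin(cap[i, contact$digit[r]], contact$position[r])
    }
  }

  cmd <- pred[, DIGIT_CHANNEL_MAP, drop = FALSE]
  closing <- cmd > thr
  vclose <- speed * (cmd - thr) / (1 - thr)

  eps <- 1e-12
  pos <- numeric(6)
  code <- matrix(2L, n, 6) # OPEN
  for (i in seq_len(n)) {
    cl <- closing[i, ]
    np <- ifelse(cl, pos + vclose[i, ] * dt, pos - speed * dt)
    np <- pmin(pmax(np, 0), cap[i, ])
    st <- integer(6)
    st[cl & np > pos + eps] <- 3L # CLOSING
    at_cap <- cl & np <= pos + eps
    st[at_cap & np >= 1 - eps] <- 4L # CLOSED
    st[at_cap & np < 1 - eps] <- 5L # STALLED (blocked by contact)
    st[!cl & np < pos - eps] <- 1L # OPENING
    st[!cl & np >= pos - eps] <- 2L # OPEN
    code[i, ] <- st
    pos <- np
  }
  out <- tibble(time = time)
  for (d in 1:6) out[[paste0("d", d)]] <- DIGIT_STATUSES[code[, d]]
  out
}

#' Simulate unreliable button reporting
#'
#' Emulates how a subject signals perceived failures with a wireless
#' button: each failure is noticed with probability `1 - button_miss_prob`;
#' a noticed failure is signalled after a positive cognitive delay (normal,
#' truncated at zero); and failures occurring between a noticed failure and
#' the end of the refractory window after its press are not signalled again.
#'
#' @param failures Failure events tibble (needs a time-ordered `time`
#'   column).
#' @param cfg A [sim_config()].
#' @return Tibble of button presses with a `time` column, time-ordered.
#' @export
simulate_buttons <- function(failures, cfg = sim_config()) {
  times <- sort(failures$time)
  presses <- numeric(0)
  blocked_until <- -Inf
  for (tt in times) {
    if (tt <= blocked_until) next
    if (runif(1) < cfg$button_miss_prob) next
    repeat {
      delay <- rnorm(1, cfg$button_delay_mean, cfg$button_delay_sd)
      if (delay >= 0) break
    }
    press <- tt + delay
    presses <- c(presses, press)
    blocked_until <- press + cfg$button_refractory
  }
  tibble(time = presses)
}

#' Scan a session for contrary-to-intent threshold crossings
#'
#' A diagnostic used to check the simulator's ground truth: finds every
#' sample at which a prediction channel crosses the actuation threshold
#' against the scripted intent — upward while the intent is rest, or
#' downward on a grasp-driven channel while the intent is power grasp.
#' Crossings within the settle window after an intent switch are
#' transitional (the signal is following the new intent) and are not
#' reported.
#'
#' @param session A `myo_session`.
#' @param threshold Actuation threshold.
#' @param settle_window Settling time (s) after `t_grasp` / `t_release`.
#' @return Tibble with columns `time`, `channel`, `direction`
#'   (`"up"`/`"down"`).
#' @export
contrary_crossings <- function(session, threshold = 0.3, settle_window = 0.5) {
  time <- session$prediction$time
  n <- length(time)
  tasks <- session$tasks
  grasp_intent <- rep(FALSE, n)
  settle <- rep(FALSE, n)
  for (k in seq_len(nrow(tasks))) {
    grasp_intent[time >= tasks$t_grasp[k] & time < tasks$t_release[k]] <- TRUE
    settle[(time >= tasks$t_grasp[k] & time < tasks$t_grasp[k] + settle_window) |
      (time >= tasks$t_release[k] & time < tasks$t_release[k] + settle_window)] <- TRUE
  }
  out <- list()
  for (ch in 1:4) {
    s <- session$prediction[[paste0("p", ch)]] > threshold
    up <- which(c(FALSE, s[-1] & !s[-n]))
    down <- which(c(FALSE, !s[-1] & s[-n]))
    ig <- if (ch <= 3) grasp_intent else rep(FALSE, n)
    sett <- if (ch <= 3) settle else rep(FALSE, n)
    bad_up <- up[!ig[up] & !sett[up]]
    bad_down <- down[ig[down] & !sett[down]]
    if (length(bad_up)) {
      out[[length(out) + 1]] <- tibble(time = time[bad_up], channel = ch, direction = "up")
    }
    if (length(bad_down)) {
      out[[length(out) + 1]] <- tibble(time = time[bad_down], channel = ch, direction = "down")
    }
  }
  if (!length(out)) {
    return(tibble(time = numeric(), channel = integer(), direction = character()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$time)
}
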