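---
title: "Detecting myocontrol instability: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting myocontrol instability: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(myoracle)
library(dplyr)
```

## The problem and the approach

In simultaneous-and-proportional (s/p) myocontrol, a regression model maps
surface-EMG features to four prediction channels in $[0, 1]$ that drive a
six-motor prosthetic hand. Predictions above an actuation threshold
($\theta = 0.3$ by the convention of the controller family this package
models) command proportional closing; below it the hand is driven to an
all-open *home configuration*. A **myocontrol failure** is an event in
which the hand starts a behavior contrary to the user's intent — a finger
closing while the user rests, or the grasp opening while the user carries
an object.

`myoracle` builds an *automatic oracle* for such failures: windows of the
prediction and hand-feedback signals are summarized by small count
features, labeled against an intent ground truth, and classified by a
class-weighted SVM. Since real subject recordings of this kind are not
generally available, the package ships a session simulator whose failures
are known exactly, so the whole pipeline can be validated end to end.

## The session model

A session holds synchronized traces (prediction, digit status), ordered
task timelines, failure instants and button presses. Each task scripts the
intent: rest on $[t_{start}, t_{grasp})$, power grasp on
$[t_{grasp}, t_{release})$, rest on $[t_{release}, t_{end}]$, which also
defines the three analysis zones Pre-Grasp, Grasp and Post-Grasp. Zone
boundaries are half-open with the switch instant belonging to the new
intent — `zone_of(t_grasp)` is `GRASP` — a deterministic tie-break that
matches the semantics of the grasp starting *at* the grasp instant.

Times are session-absolute seconds; serialization writes doubles at 17
significant digits, so `write_session()` followed by `read_session()` is
the identity, bit for bit (the traces are re-read with base R's
correctly-rounded `strtod`). Status strings are serialized uppercase and
parsed case-insensitively. The digit-status feedback is assumed to be
available on the prediction timebase; hardware reports it asynchronously,
but nothing in the method depends on the feedback's native rate.

## What the simulator emulates

`generate_session()` is a deterministic function of its `sim_config()`.
The defaults *are* the study conditions the package targets; they were
fixed once and are not tuned against test outcomes:

* **20 tasks** per session at **100 Hz**. The sampling rate of the
  prediction/status streams is a free choice (the controller family reads
  sEMG at 200 Hz, but the prediction rate is not dictated by it); 100 Hz
  resolves the shortest 0.5 s analysis window with 50 samples while
  keeping desk-scale sessions cheap.
* **Zone durations** drawn from truncated normals with means 6 s
  (Pre-Grasp), 8 s (Grasp) and 12 s (Post-Grasp), SD 1 s, floor 2 s: the
  Post-Grasp zone is the longest on average, as observed in this task
  family. Tasks are separated by a 2 s seated pause; windows never span
  tasks.
* **Failure intensities** per task and zone of 0.65 / 0.65 / 1.7
  (Pre : Grasp : Post = 1 : 1 : 2.5), i.e. about three failures per task —
  within the range such experiments report. Counts are Poisson; placement
  is uniform within Pre-Grasp and Grasp and mid-zone concentrated
  (Beta(2, 2)) within Post-Grasp, reproducing the qualitative pattern that
  failures cluster in the middle of the carry-back phase. These choices
  are qualitative emulation, not a numerical reconstruction of any
  subject's data.
* **Signal shape.** Channels 1–3 (thumb flexion, index, coupled
  middle/ring/little) follow the grasp intent between a rest level of 0.05
  and a grasp level of 0.7 through raised-cosine ramps of 0.3 s; channel 4
  (thumb abduction) stays at rest in this task. AR(1) noise
  ($\varphi = 0.95$, SD 0.02) makes the traces band-limited rather than
  white. Outside failures and the 0.5 s settling window after an intent
  switch, the signal is clamped 0.03 clear of the threshold: the
  *only* contrary-to-intent threshold crossings in a generated session are
  the injected ones, which is what makes the ground truth exact.
* **Failures** inject a Hann-windowed sinusoidal transient (1.2 s, 3 Hz)
  normalized to a peak excursion of 0.55, so a rest-zone transient rises
  above the threshold (spurious close) and a grasp transient dips below it
  (spurious open, on a grasp-driven channel). Temporally overlapping
  transients are assigned distinct channels. The recorded failure time is
  the first sample at which the transient crosses the threshold against
  intent — the earliest machine-observable analogue of the "first video
  frame" convention used when failures are annotated manually.
* **The hand** integrates each digit's position: full-speed opening below
  the threshold, proportional closing speed
  $v = v_{max}(p - \theta)/(1 - \theta)$ above it, with $v_{max} = 1.2$
  full travels per second (the order of magnitude of a motorized
  prosthetic finger). Statuses are `CLOSING`/`OPENING` while moving,
  `OPEN`/`CLOSED` at the limits, and `STALLED` when commanded closed
  against object contact (at 60% closure during the Grasp zone by
  default). The electromechanical smoothing is what differentiates SC from
  TC: prediction oscillations faster than the hand's response, or against
  a stalled digit, leave no trace in the status stream.
* **Buttons.** A failure is noticed with probability 0.85; a noticed
  failure is signalled after a normal delay (mean 1.5 s, SD 0.7 s,
  truncated at zero), and failures occurring between a noticed failure and
  3 s after its press are not signalled again. This reproduces the four
  recurring unreliability behaviors of human failure reporting (single
  signal per episode, structural delay, unreported failures during the
  delay, unnoticed failures). Button presses are *not* used for labeling —
  labels come from the ground-truth instants — but the model is kept
  first-class because any attempt to learn from online self-reports must
  face exactly these artifacts.

What the simulator does **not** emulate: raw sEMG and its preprocessing,
the regression controller itself (predictions are generated directly),
model updates after catastrophic failures, drift or fatigue within a
session, and annotation noise in the ground truth. Passing tests on
synthetic sessions therefore demonstrate the correctness and operating
characteristics of the pipeline — not field performance on patients, which
is typically much worse than the clean-session upper bounds reported here.

## Features and labeling

Windows of 0.5, 1 or 3 s tile each task from `t_start`, with a step of one
window or half a window; a trailing partial window is dropped so counts
are comparable across window sizes. Per window and channel:

* **TC** — the number of crossings of the actuation threshold by the
  prediction signal (both directions; a sample exactly at the threshold
  counts as below, a deterministic tie-break);
* **SC** — the number of transitions of the *filtered digit status*:
  closing/closed $\to$ 1 ("flexing"), opening/open $\to$ 0 ("extending"),
  with `STALLED` holding the previous value (a stall preserves the last
  motion direction and adds no phantom transition; a leading stall maps
  to 0). The six digits collapse to the four prediction channels via their
  representative digits (thumb, index, middle-of-coupled-group, thumb
  abduction);
* **TC+SC** — the 8-dimensional concatenation.

A window is labeled `1` (failure) iff a failure instant lies in its
half-open span. Three feature types, three lengths and two overlaps give
the 18 canonical feature sets per subject.

## The detector

The classifier is an RBF-kernel SVM with per-class regularization:
$C_0 = 1$ for the success class and $C_1 = n_0/n_1$ for the failure class,
where $n_0, n_1$ are the training counts. Failure windows are the minority
(more so for short windows), and up-weighting the minority by the class
ratio is the standard remedy; the weight is recomputed from each training
split. Evaluation is a stratified nested 10-fold cross-validation: the
inner loop grid-searches $(C, \gamma)$ over $C \in 2^{\{-5,-3,\dots,15\}}$
and $\gamma \in 2^{\{-15,-13,\dots,3\}}$ (the customary libsvm sweep, in
steps of powers of four), selecting by mean inner balanced error rate with
ties broken toward smaller $C$ then smaller $\gamma$ (prefer smoother
models); the winner is refit on the outer training set and applied to the
held-out fold. Design choices worth stating:

* **Stratified folds.** At these imbalance levels unstratified folds can
  end up single-class, which makes the BER undefined; stratification is
  the only reasonable reading of a 10-fold CV on such data.
* **Feature scaling** uses the training split's mean and variance only,
  inside every split — count features of different window lengths are
  scale-incomparable, and leaking test statistics would bias the search.
* **Selection metric** is the BER, not accuracy, consistent with the
  imbalance-aware evaluation; inner folds whose test part lacks a class
  are skipped.
* **ROC from decision values.** The curve sweeps the SVM decision values
  rather than fitted class probabilities: any strictly monotone transform
  of the scores yields the same curve, and decision values avoid the
  internal cross-validation nondeterminism of probability calibration.
  Scores are oriented so that higher means more success-like.

Evaluation conventions: myocontrol *success* is the positive condition.
The rate matrix is the row-normalized confusion matrix
($TPR = N_{TP}/(N_{TP}+N_{FN})$, $FPR = N_{FP}/(N_{FP}+N_{TN})$), and

$$\mathrm{BER} = \frac{100}{2}\left(\frac{N_{FN}}{N_{TP}+N_{FN}} +
\frac{N_{FP}}{N_{FP}+N_{TN}}\right).$$

The AUC is computed by the rank formula and therefore equals the
normalized Mann–Whitney statistic with ties counted one half; mean ROC
curves are vertical averages of linearly interpolated curves on a fixed
101-point FPR grid. One vocabulary note: descriptions of this labeling
scheme sometimes flip which class carries the value 0 between the labeling
and the classifier-weight conventions; this package fixes **failure = 1 =
minority class** throughout, and gives that class the $n_0/n_1$ up-weight,
which is the only assignment under which the weight formula acts as a
minority up-weight.

## The analysis layer

* **Zone summaries** assign each failure to its zone and to a
  zone-normalized time bin, $u = (t - t_{zone})/\Delta_{zone}$, with 10
  bins per zone (a bin count fine enough to show the mid-zone
  concentration at these event counts without going sparse).
* **Trend diagnostics** fit an ordinary least-squares line and report
  Cook's distances; the implementation uses the standard
  leverage/residual form and is tested to agree with brute-force
  leave-one-out refits to $10^{-10}$. A perfect fit reports zero distances
  (the standardized form is 0/0 there).
* **Group comparison** runs Shapiro–Wilk per group and the two-sided
  Wilcoxon rank-sum test — exact when the combined sample is at most 25
  and untied, normal approximation with continuity correction otherwise.
  The reported $W$ is the rank sum of the first group (the convention of
  MATLAB's `ranksum`), not R's U-style statistic.
* **ANOVA** assumes the balanced full factorial (every subject crossed
  with all 18 sets), on which classical sequential sums of squares equal
  partial ones; unbalanced tables are rejected rather than silently
  re-weighted. The three-way model includes all interactions — with $N$
  subjects the residual degrees of freedom are $18(N-1)$, e.g. $(2, 90)$
  main-effect tests at $N = 6$. The one-way reduction on feature type
  ($df = (2, 18N - 3)$) is followed by Tukey HSD. A constant response
  table reports $F = 0$, $p = 1$ rather than 0/0.
* **Power analysis** follows the fixed-effects ANOVA convention of
  standard power software: $\lambda = f^2 N$, $df_{den} = N - k$ for $k$
  design cells, central-F critical value at $1-\alpha$, power from the
  noncentral F. Cohen's $f$ comes from sums of squares,
  $f = \sqrt{SS_{effect}/SS_{error}}$. The a-priori search returns the
  smallest integer $N$ whose power reaches the target, with no rounding
  to group multiples. Note one boundary subtlety: when the power at some
  $N$ is within rounding distance below the target (e.g. 0.79998), this
  strict search returns $N + 1$ while software that rounds the displayed
  power to two decimals reports $N$; the package keeps the strict
  inequality.

```{r power}
posthoc_power(f = 0.2496, alpha = 0.05, n_total = 108, df_num = 2, n_groups = 18)
required_sample_size(f = 0.2496, alpha = 0.05, df_num = 2, n_groups = 18,
                     target_power = 0.8)
```

## A small end-to-end run

```{r pipeline}
session <- generate_session(sim_config(seed = 1, n_tasks = 8, sample_rate = 50))
features <- extract_dataset(session, window_length = 3, overlap = "none",
                            feature_type = "sc")
cv <- nested_cv(features, grid_cost = c(1, 100), grid_gamma = c(0.01, 0.25),
                seed = 7)
glance(cv)
```

The reduced problem sizes here (8 tasks, 50 Hz, a 2×2 grid) are the
vignette's choice to keep the document quick to build; the package's test
suite exercises the same code paths at 20 tasks, 100 Hz and the full
hyperparameter sweep.

## Known limitations

* Synthetic sessions are separable far beyond what subject data allows;
  BER/AUC values on them are pipeline checks, not performance claims.
* The simulator's failure taxonomy is binary (spurious close / spurious
  open); real instability includes partial, slow and compound behaviors.
* The oracle is offline: windows are classified after the fact, and no
  claim is made about the latency of an online implementation beyond the
  window length itself.
* Per-subject modeling only: no pooling of training data across subjects,
  matching how such evaluations are run, but leaving cross-subject
  generalization unexplored.
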