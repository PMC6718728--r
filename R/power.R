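#' Cohen's f from sums of squares
#'
#' Effect size `f = sqrt(ss_effect / ss_error)` of an ANOVA effect.
#'
#' @param ss_effect Effect sum of squares (>= 0).
#' @param ss_error Error sum of squares (> 0).
#' @return Cohen's f.
#' @examples
#' cohens_f_from_ss(25, 100)
#' @export
cohens_f_from_ss <- function(ss_effect, ss_error) {
  if (ss_error <= 0) abort("ss_error must be positive")
  if (ss_effect < 0) abort("ss_effect must be non-negative")
  sqrt(ss_effect / ss_error)
}

#' Post-hoc power of a fixed-effects ANOVA main effect
#'
#' Power of the F test of one main effect in a fixed-effects factorial
#' ANOVA, following the noncentral-F convention of standard power software:
#' noncentrality `lambda = f^2 * n_total`, denominator degrees of freedom
#' `n_total - n_groups` (groups = design cells), critical value the central
#' F quantile at `1 - alpha`, and power the upper tail of the noncentral F
#' at that critical value.
#'
#' @param f Cohen's effect size (>= 0).
#' @param alpha Significance level in (0, 1).
#' @param n_total Total sample size.
#' @param df_num Numerator degrees of freedom of the effect.
#' @param n_groups Number of design cells.
#' @return One-row tibble with the query, `lambda`, `df_den`, `f_crit` and
#'   `power`.
#' @examples
#' posthoc_power(f = 0.587, alpha = 0.001, n_total = 108, df_num = 2, n_groups = 3)
#' @export
posthoc_power <- function(f, alpha, n_total, df_num, n_groups) {
  if (f < 0) abort("f must be non-negative")
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  if (n_total <= n_groups) abort("n_total must exceed n_groups")
  if (df_num < 1) abort("df_num must be at least 1")
  lambda <- f^2 * n_total
  df_den <- n_total - n_groups
  f_crit <- qf(1 - alpha, df_num, df_den)
  tibble(
    f = f, alpha = alpha, n_total = as.integer(n_total),
    df_num = as.integer(df_num), n_groups = as.integer(n_groups),
    lambda = lambda, df_den = as.integer(df_den), f_crit = f_crit,
    power = 1 - pf(f_crit, df_num, df_den, ncp = lambda)
  )
}

#' A-priori total sample size for a target power
#'
#' Smallest integer total sample size whose post-hoc power (see
#' [posthoc_power()]) reaches `target_power`, found by incrementing from
#' the minimum feasible size `n_groups + 1`. No rounding to group multiples
#' is applied.
#'
#' @inheritParams posthoc_power
#' @param target_power Required power in (0, 1).
#' @param n_max Search cap.
#' @return The required total sample size (integer).
#' @examples
#' required_sample_size(f = 0.2496, alpha = 0.001, df_num = 2, n_groups = 18,
#'                      target_power = 0.8)
#' @export
required_sample_size <- function(f, alpha, df_num, n_groups, target_power,
                                 n_max = 1e6) {
  if (target_power <= 0 || target_power >= 1) {
    abort("target_power must lie in (0, 1)")
  }
  if (f <= 0) {
    if (target_power > alpha) abort("unattainable: f = 0 cannot exceed power alpha")
    return(as.integer(n_groups + 1))
  }
  n <- n_groups + 1
  while (n <= n_max) {
    if (posthoc_power(f, alpha, n, df_num, n_groups)$power >= target_power) {
      return(as.integer(n))
    }
    n <- n + 1
  }
  abort("target power not reached within the search cap")
}
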