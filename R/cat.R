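#' Constant attention task configuration
#'
#' The work unit is a press-and-hold, release-on-prompt trial taking 7.3 s on
#' average. Success requires the simulated reaction time to fall inside an
#' adaptive window which the task controller widens on failure
#' (`window * window_up`) and narrows on success (`window * window_down`),
#' a weighted up-down staircase. Its equilibrium success probability solves
#' `p log(window_down) + (1 - p) log(window_up) = 0`; the defaults
#' (1.06, 0.98) equilibrate near 0.75.
#'
#' Reaction times are lognormal; the optional impairment factor multiplies
#' them (e.g. to model alcohol-induced slowing), which the staircase
#' compensates by widening the window.
#'
#' @param mean_trial_s mean trial duration, seconds.
#' @param trial_sd_s SD of trial duration, seconds.
#' @param success_target nominal staircase equilibrium success probability.
#' @param window_up multiplicative window factor on failure (> 1).
#' @param window_down multiplicative window factor on success (in (0, 1]).
#' @param window_init_s initial window, seconds.
#' @param rt_median_s median reaction time, seconds.
#' @param rt_sdlog lognormal sdlog of reaction times.
#' @param impair_per_mg_dl fractional reaction-time slowing per mg/dL BrAC.
#' @return An object of class `cat_config`.
#' @export
cat_config <- function(mean_trial_s = 7.3, trial_sd_s = 1.2,
                       success_target = 0.75,
                       window_up = 1.06, window_down = 0.98,
                       window_init_s = 0.40,
                       rt_median_s = 0.35, rt_sdlog = 0.25,
                       impair_per_mg_dl = 0.002) {
  if (mean_trial_s <= 0) .stopf("mean_trial_s must be positive")
  if (success_target <= 0 || success_target >= 1)
    .stopf("success_target must lie in (0, 1)")
  if (window_up < 1) .stopf("window_up must be at least 1")
  if (window_down <= 0 || window_down > 1)
    .stopf("window_down must lie in (0, 1]")
  ## window_up = window_down = 1 disables adaptation (useful for exact
  ## timing fixtures); otherwise window_up must strictly exceed 1
  if (window_up == 1 && window_down < 1)
    .stopf("window_up = 1 requires window_down = 1 (no adaptation)")
  structure(list(mean_trial_s = mean_trial_s, trial_sd_s = trial_sd_s,
                 success_target = success_target,
                 window_up = window_up, window_down = window_down,
                 window_init_s = window_init_s,
                 rt_median_s = rt_median_s, rt_sdlog = rt_sdlog,
                 impair_per_mg_dl = impair_per_mg_dl),
            class = "cat_config")
}

#' Equilibrium success probability of the staircase
#'
#' Detailed balance of the multiplicative up-down rule on the log scale:
#' `p = log(window_up) / (log(window_up) - log(window_down))`.
#'
#' @param cat a [cat_config()].
#' @return The equilibrium success probability.
#' @export
cat_equilibrium_success <- function(cat) {
  stopifnot(inherits(cat, "cat_config"))
  if (cat$window_up == 1 && cat$window_down == 1) return(NA_real_)
  if (cat$window_down == 1) return(1)
  log(cat$window_up) / (log(cat$window_up) - log(cat$window_down))
}

#' Run one attention-task trial
#'
#' Draws a trial duration (truncated normal, at least 2 s) and a reaction
#' time (lognormal, scaled by `impairment`); the trial succeeds when the
#' reaction time is at most `window`. Uses the current RNG stream.
#'
#' @param cat a [cat_config()].
#' @param window current adaptive window, seconds (may be `Inf`).
#' @param impairment multiplicative reaction-time slowing factor (>= 1 for
#'   impairment; 1 = unimpaired).
#' @return A list with `duration_s`, `success`, `rt_s`.
#' @export
run_cat_trial <- function(cat, window, impairment = 1) {
  stopifnot(inherits(cat, "cat_config"))
  duration <- max(2, rnorm(1, cat$mean_trial_s, cat$trial_sd_s))
  rt <- rlnorm(1, log(cat$rt_median_s), cat$rt_sdlog) * impairment
  list(duration_s = duration, success = rt <= window, rt_s = rt)
}

#' Adapt the staircase window after a trial
#'
#' @param cat a [cat_config()].
#' @param window current window, seconds.
#' @param success logical trial outcome.
#' @return The updated window.
#' @export
adapt_window <- function(cat, window, success) {
  stopifnot(inherits(cat, "cat_config"))
  if (window <= 0) .stopf("window must be positive")
  window * if (success) cat$window_down else cat$window_up
}
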