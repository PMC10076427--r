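#' Progressive-ratio work schedule
#'
#' The number of correct attention-task trials required to complete the k-th
#' work-set grows geometrically: `round(n1 * ratio^(k-1))`. The progression
#' is identical for alcohol and saline rewards but accounted separately.
#'
#' @param n1 trials required for the first work-set (>= 1).
#' @param ratio progression factor (> 1).
#' @param mean_trial_s mean duration of one trial, seconds.
#' @return An object of class `work_schedule`.
#' @seealso [calibrate_schedule()], [required_trials()], [futility_index()]
#' @export
work_schedule <- function(n1, ratio, mean_trial_s = 7.3) {
  if (n1 < 1) .stopf("n1 must be at least 1")
  if (ratio <= 1) .stopf("ratio must exceed 1")
  if (mean_trial_s <= 0) .stopf("mean_trial_s must be positive")
  structure(list(n1 = round(n1), ratio = ratio, mean_trial_s = mean_trial_s),
            class = "work_schedule")
}

#' @export
print.work_schedule <- function(x, ...) {
  cat(sprintf("<work_schedule> n1 = %d, ratio = %.4f, mean trial %.1f s\n",
              x$n1, x$ratio, x$mean_trial_s))
  cat("  requirements 1..15:", paste(required_trials(x, 1:15), collapse = " "),
      "\n")
  invisible(x)
}

#' Calibrate the geometric schedule to two anchor durations
#'
#' The exact progression table is a property of the (compiled) laboratory
#' control software; only two typical durations are public knowledge: the
#' first work-set takes about 30 s and the fifteenth about 23 min, at a mean
#' trial duration of 7.3 s. The calibration converts both anchors to trial
#' counts (`n1 = round(30/7.3) = 4`, `n15 = round(23*60/7.3) = 189`) and
#' solves `n1 * ratio^(last_index - 1) = n15` for the ratio (about 1.3171).
#'
#' @param first_duration_s duration anchor for work-set 1, seconds.
#' @param last_index index of the second anchor work-set.
#' @param last_duration_min duration anchor for that work-set, minutes.
#' @param mean_trial_s mean trial duration, seconds.
#' @return A [work_schedule()].
#' @examples
#' calibrate_schedule()  # n1 = 4, ratio ~ 1.317
#' @export
calibrate_schedule <- function(first_duration_s = 30, last_index = 15,
                               last_duration_min = 23, mean_trial_s = 7.3) {
  if (first_duration_s <= 0 || last_duration_min <= 0 || mean_trial_s <= 0)
    .stopf("durations must be positive")
  if (last_index < 2) .stopf("last_index must be at least 2")
  n1 <- round(first_duration_s / mean_trial_s)
  n_last <- round(last_duration_min * 60 / mean_trial_s)
  if (n1 < 1) .stopf("first anchor shorter than one trial")
  if (n_last <= n1)
    .stopf("infeasible calibration: implied ratio would not exceed 1")
  ratio <- (n_last / n1)^(1 / (last_index - 1))
  work_schedule(n1 = n1, ratio = ratio, mean_trial_s = mean_trial_s)
}

#' Required trials for a work-set
#'
#' @param schedule a [work_schedule()].
#' @param k work-set index (vectorised, each >= 1).
#' @return Integer vector of required correct trials, strictly increasing
#'   in `k`.
#' @examples
#' required_trials(calibrate_schedule(), c(1, 2, 15))  # 4 5 189
#' @export
required_trials <- function(schedule, k) {
  stopifnot(inherits(schedule, "work_schedule"))
  if (any(k < 1) || any(k != round(k))) .stopf("k must be integer >= 1")
  as.integer(round(schedule$n1 * schedule$ratio^(k - 1)))
}

#' Futility index of a schedule
#'
#' The work-set index at which the expected work time, at the prescribed
#' inter-reward BrAC decline, costs at least as much BrAC as one reward
#' restores: the smallest `k` with
#' `required_trials(k) * mean_trial_s / 60 * decline >= reward_increment`.
#' Beyond this point BrAC falls despite continuous work.
#'
#' @param schedule a [work_schedule()].
#' @param reward_increment BrAC gain per alcohol reward, mg/dL.
#' @param decline inter-reward BrAC decline rate, mg/dL/min.
#' @param max_k search bound.
#' @return The index, or `Inf` if no finite index exists (e.g. `decline = 0`).
#' @examples
#' futility_index(calibrate_schedule())  # 14
#' @export
futility_index <- function(schedule, reward_increment = 13, decline = 0.8,
                           max_k = 1000) {
  stopifnot(inherits(schedule, "work_schedule"))
  if (reward_increment <= 0) .stopf("reward_increment must be positive")
  if (decline <= 0) return(Inf)
  ## double arithmetic: the geometric requirement overflows integers quickly
  for (k in seq_len(max_k)) {
    trials <- round(schedule$n1 * schedule$ratio^(k - 1))
    if (trials * schedule$mean_trial_s / 60 * decline >= reward_increment)
      return(k)
  }
  Inf
}
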