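## Shared fixtures for the test suite. Everything is built in code.

default_male <- function(id = "s001")
  subject_profile(id, "male", 30, 180, 80)

default_female <- function(id = "s002")
  subject_profile(id, "female", 40, 165, 60)

## one-compartment parameters (f_per = 0, k_per = 0): the closed-form regime
one_comp_params <- function(vd = 45.8, vmax = 0, km = 0.1)
  pk_params(vd = vd, vmax = vmax, km = km, k_per = 0, f_per = 0)

## attention task with no randomness in duration and a non-adapting,
## always-succeeding window: work-set timing becomes exact arithmetic
deterministic_cat <- function()
  cat_config(trial_sd_s = 0, window_up = 1, window_down = 1,
             window_init_s = Inf, impair_per_mg_dl = 0)

## noiseless session configuration (no breathalyzer noise)
noiseless_config <- function(...)
  session_config(brac_noise_sd = 0, ...)

## hand-built event log wrapped as an asa_session, for cumulative_work tests
fixture_session <- function(events, subject = "fx", session_index = 1) {
  structure(list(subject = subject, session_index = session_index,
                 events = events, drug_level = 0),
            class = "asa_session")
}

## event-log row builder (handles zero-length input)
ev_rows <- function(t, kind, reward_kind = "none", priming = FALSE) {
  n <- length(t)
  data.frame(t = t, kind = rep(kind, length.out = n),
             reward_kind = rep(reward_kind, length.out = n),
             set_index = rep(NA_integer_, n),
             priming = rep(priming, length.out = n))
}

## brute-force Cohen's d from raw vectors (independent of the package path)
brute_cohens_d <- function(x, y) {
  sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
               (length(x) + length(y) - 2))
  (mean(x) - mean(y)) / sp
}
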