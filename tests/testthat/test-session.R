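test_that("session replay with the same seed is bit-identical", {
  prof <- default_male()
  a <- run_session(prof, seed = 123)
  b <- run_session(prof, seed = 123)
  expect_identical(a$events, b$events)
  expect_identical(a$brac, b$brac)
  expect_identical(a$assessments, b$assessments)
  c <- run_session(prof, seed = 124)
  expect_false(identical(a$events, c$events))
})

test_that("every completed work-set contains exactly its required successes", {
  prof <- default_male()
  s <- run_session(prof, seed = 55)
  e <- s$events
  done <- e[e$kind == "workset_complete" & !e$priming, ]
  sched <- s$schedule
  for (r in seq_len(nrow(done))) {
    kind <- done$reward_kind[r]; k <- done$set_index[r]
    start <- max(e$t[e$kind == "workset_start" & e$reward_kind == kind &
                       e$set_index == k & !e$priming])
    n_succ <- sum(e$kind == "trial_success" & e$reward_kind == kind &
                    e$set_index == k & !e$priming &
                    e$t > start - 1e-9 & e$t <= done$t[r] + 1e-9)
    expect_identical(n_succ, as.integer(required_trials(sched, k)))
  }
})

test_that("scripted event counts match an independent closed-form schedule", {
  ## deterministic task: every trial succeeds and lasts exactly 7.3 s, the
  ## agent always works for alcohol with zero latency, no gate pressure
  ## (high safety limit), so completion times are pure arithmetic
  prof <- default_male()
  cfg <- session_config(brac_noise_sd = 0, safety_limit = 1e6)
  s <- run_session(prof, agent = scripted_agent("always_alcohol"),
                   cat = deterministic_cat(), config = cfg, seed = 1)
  ws <- calibrate_schedule()
  ## closed form: set k needs n_k trials of 7.3 s plus a 3-min reward
  k <- 1:40
  cum <- cumsum(required_trials(ws, k) * 7.3 / 60 + 3)
  m_expected <- sum(cum <= 150)
  e <- s$events
  m_sim <- sum(e$kind == "workset_complete" & !e$priming)
  expect_identical(m_sim, m_expected)
  ## cWFA equals the trials finished by 150 min
  full_sets <- sum(required_trials(ws, seq_len(m_expected)))
  t_left <- 150 - cum[m_expected]
  partial <- floor(t_left * 60 / 7.3)
  expect_identical(s$cwfa, as.integer(full_sets + partial))
})

test_that("BrAC falls at the prescribed rate through the waiting period", {
  prof <- default_male()
  cfg <- session_config(brac_noise_sd = 0, record_interval_min = 0.1)
  s <- run_session(prof, agent = scripted_agent("never_work"),
                   cat = deterministic_cat(), config = cfg, seed = 3)
  e <- s$events
  t_prim_end <- max(e$t[e$kind == "reward_end" & e$priming])
  wait <- 0 - t_prim_end
  expect_gt(wait, 1)
  b <- s$brac
  w <- b$t_min >= t_prim_end + 0.2 & b$t_min <= 0
  slope <- coef(lm(brac_mg_dl ~ t_min, b[w, ]))[[2]]
  expect_equal(slope, -0.8, tolerance = 0.15)
})

test_that("the mean BrAC trajectory rises first and flattens late", {
  ## steadily working agent: ascending-then-plateau shape
  prof <- default_male()
  slopes <- sapply(1:5, function(k) {
    s <- run_session(prof, agent = scripted_agent("always_alcohol"),
                     seed = 600 + k)
    b <- s$brac
    c(coef(lm(brac_mg_dl ~ t_min, b[b$t_min >= 0 & b$t_min <= 60, ]))[[2]],
      coef(lm(brac_mg_dl ~ t_min, b[b$t_min >= 100 & b$t_min <= 150, ]))[[2]])
  })
  expect_gt(mean(slopes[1, ]), 0)
  expect_lte(mean(slopes[2, ]), 0)
})

test_that("sessions respect the safety limit and pump range", {
  prof <- default_male()
  for (sd_ in 1:3) {
    s <- run_session(prof, agent = scripted_agent("always_alcohol"),
                     seed = 70 + sd_)
    expect_lte(max(s$brac$brac_mg_dl), 180)
    expect_true(all(s$brac$infusion_ml_h >= 0 &
                      s$brac$infusion_ml_h <= 1998))
  }
})

test_that("the log covers the whole session with all assessments", {
  prof <- default_male()
  s <- run_session(prof, seed = 11)
  expect_lte(min(s$brac$t_min), -25 + 1e-9)
  expect_gte(max(s$brac$t_min), 150 - 0.5)
  expect_identical(nrow(s$assessments), 4L)
  expect_equal(s$assessments$t, c(-25, 15, 75, 150))
  expect_false(is.unsorted(s$events$t))
  ## peak is at least the mean
  expect_gte(s$peak_brac, s$mean_brac)
})

test_that("cumulative work is additive over the phase windows", {
  prof <- default_male()
  s <- run_session(prof, seed = 21)
  expect_identical(
    cumulative_work(s, "alcohol"),
    cumulative_work(s, "alcohol", c(0, 75)) +
      cumulative_work(s, "alcohol", c(75, 150)))
  expect_identical(
    cumulative_work(s, "saline"),
    cumulative_work(s, "saline", c(0, 75)) +
      cumulative_work(s, "saline", c(75, 150)))
  expect_error(cumulative_work(s, "alcohol", c(-10, 75)), "window")
})

test_that("cumulative work counts fixture events as specified", {
  ev <- rbind(
    ev_rows(seq(1, 70, length.out = 37), "trial_success", "alcohol"),
    ev_rows(seq(80, 140, length.out = 12), "trial_success", "alcohol"),
    ev_rows(seq(5, 60, length.out = 6), "trial_success", "saline"),
    ev_rows(seq(2, 50, length.out = 9), "trial_fail", "alcohol"),
    ev_rows(-5, "trial_success", "alcohol", priming = TRUE))
  s <- fixture_session(ev)
  expect_identical(cumulative_work(s, "alcohol", c(0, 75)), 37L)
  expect_identical(cumulative_work(s, "alcohol", c(75, 150)), 12L)
  expect_identical(cumulative_work(s, "alcohol"), 49L)
  expect_identical(cumulative_work(s, "saline"), 6L)
  s0 <- fixture_session(ev_rows(numeric(0), character(0)))
  expect_identical(cumulative_work(s0, "alcohol"), 0L)
})
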