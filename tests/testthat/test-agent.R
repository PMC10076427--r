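test_that("subjective state returns to baseline at zero exposure", {
  p <- agent_params()
  s <- subjective_state(stimulation = 20, sedation = 10, wellbeing = 50,
                        desire = 30, drunkenness = 0)
  s2 <- update_subjective(s, p, brac = 0, brac_slope = 0)
  expect_equal(s2$stimulation, 20)
  expect_equal(s2$wellbeing, 50)
  expect_equal(s2$desire, 30)
  ## displaced state relaxes toward baseline
  s3 <- subjective_state(stimulation = 60, desire = 70)
  s4 <- update_subjective(s3, p, 0, 0)
  expect_lt(s4$stimulation, 60)
  expect_lt(s4$desire, 70)
  expect_gt(s4$stimulation, 20)
})

test_that("drug attenuation halves the stimulation increment at delta*L = 0.5", {
  p0 <- agent_params(drug_attenuation = 0)
  p5 <- agent_params(drug_attenuation = 0.01)
  s <- subjective_state()
  inc0 <- update_subjective(s, p0, 50, 4.33, 0)$stimulation - s$stimulation
  inc5 <- update_subjective(s, p5, 50, 4.33, 50)$stimulation - s$stimulation
  expect_equal(inc5 / inc0, 0.5, tolerance = 1e-10)
})

test_that("a falling BrAC strictly raises desire", {
  p <- agent_params()
  s <- subjective_state()
  s2 <- update_subjective(s, p, 80, -0.8)
  expect_gt(s2$desire, s$desire)
})

test_that("all subjective scales stay within [0, 100] under extreme inputs", {
  p <- agent_params()
  set.seed(5)
  s <- subjective_state()
  for (i in 1:300) {
    s <- update_subjective(s, p, runif(1, 0, 400), runif(1, -50, 50),
                           drug_level = runif(1, 0, 100), dt = runif(1, 0.5, 5))
    vals <- unlist(s[c("stimulation", "sedation", "wellbeing", "desire",
                       "drunkenness")])
    expect_true(all(vals >= 0 & vals <= 100))
  }
})

test_that("temperature zero reduces the decision to an argmax", {
  p <- agent_params(temperature = 0, work_propensity = 5)  # alcohol dominates
  s <- subjective_state()
  ctx <- list(t_min = 0, brac = 0, eligible_alcohol = TRUE, drug_level = 0)
  expect_identical(decide_action(p, s, ctx), "work_alcohol")
})

test_that("an ineligible alcohol reward is never chosen", {
  p <- agent_params(work_propensity = 5)
  s <- subjective_state()
  ctx <- list(t_min = 0, brac = 175, eligible_alcohol = FALSE, drug_level = 0)
  set.seed(1)
  acts <- replicate(300, decide_action(p, s, ctx))
  expect_false("work_alcohol" %in% acts)
})

test_that("equal utilities give near-uniform choice frequencies", {
  ## neutralise every utility channel so all three actions tie at 0
  p <- agent_params(work_propensity = 0, water_bonus = 0, pos_weight = 0,
                    av_weight = 0, neg_weight = 0, fatigue_rate = 0,
                    temperature = 1)
  s <- subjective_state()
  ctx <- list(t_min = 0, brac = 0, eligible_alcohol = TRUE, drug_level = 0)
  set.seed(42)
  acts <- replicate(10000, decide_action(p, s, ctx))
  freq <- table(acts) / length(acts)
  expect_equal(unname(freq[["work_alcohol"]]), 1 / 3, tolerance = 0.05)
  expect_equal(unname(freq[["work_water"]]), 1 / 3, tolerance = 0.05)
  expect_equal(unname(freq[["rest"]]), 1 / 3, tolerance = 0.05)
})

test_that("scripted agents follow their policies inside full sessions", {
  prof <- default_male()
  ## always-alcohol: no saline work at all
  sa <- run_session(prof, agent = scripted_agent("always_alcohol"), seed = 7)
  expect_identical(sa$cwfs, 0L)
  expect_gt(sa$cwfa, 0)
  ## never-work: no voluntary events beyond rests/assessments, BrAC decays
  nw <- run_session(prof, agent = scripted_agent("never_work"), seed = 8)
  expect_identical(nw$cwfa, 0L)
  expect_identical(nw$cwfs, 0L)
  vwr <- nw$events[!nw$events$priming & nw$events$t >= 0, ]
  expect_true(all(vwr$kind %in% c("rest_start", "rest_end", "assessment",
                                  "brac_reading")))
  ## elimination-limited decay: ~14 mg/dL/h clears most but not all of the
  ## ~45 mg/dL priming exposure within the session
  expect_lt(tail(nw$brac$brac_mg_dl, 1), 15)
  expect_lt(tail(nw$brac$brac_mg_dl, 1), 0.3 * nw$peak_brac)
  expect_error(scripted_agent("dance"), "arg")
})

test_that("alternation advances the two progressions in lockstep", {
  prof <- default_male()
  al <- run_session(prof, agent = scripted_agent("alternating"),
                    cat = deterministic_cat(), config = noiseless_config(),
                    seed = 9)
  e <- al$events
  done <- e[e$kind == "workset_complete" & !e$priming, ]
  k_alc <- sum(done$reward_kind == "alcohol")
  k_sal <- sum(done$reward_kind == "saline")
  expect_lte(abs(k_alc - k_sal), 1)
  ## both kinds were asked for the same requirement at the same index
  for (kind in c("alcohol", "saline")) {
    idx <- done$set_index[done$reward_kind == kind]
    expect_identical(sort(idx), seq_along(idx))
  }
})

test_that("expected cumulative work is nonincreasing in the drug effect", {
  ## matched seeds across attenuation levels
  prof <- default_male()
  n <- 200
  levels <- c(0, 28, 55)  # delta = 0.01 -> delta*L of 0, 0.28, 0.55
  means <- sapply(levels, function(lv) {
    mean(vapply(seq_len(n), function(k) {
      ag <- agent_params(drug_attenuation = 0.01)
      run_session(prof, agent = ag, drug_level = lv, seed = 31000 + k)$cwfa
    }, 0))
  })
  expect_true(all(diff(means) < 0))
})
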