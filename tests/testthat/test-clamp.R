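test_that("the target trajectory follows the prescribed reward dynamics", {
  tr <- target_trajectory(0, 50)
  tr <- extend_target_for_reward(tr, 10, "alcohol")
  ## at t = 10 the target has declined to 42; the ramp tops out at 13 above
  expect_equal(target_at(tr, 10), 50 - 0.8 * 10)
  expect_equal(target_at(tr, 13), 42 + 13)
  ## without rewards: linear decline
  tr2 <- target_trajectory(0, 50)
  expect_equal(target_at(tr2, 20), 42 + 0 - 8 + 0)  # 50 - 0.8*20 = 34
  expect_equal(target_at(tr2, 20), 34)
  ## floor at zero
  tr3 <- target_trajectory(0, 4)
  expect_equal(target_at(tr3, 10), 0)
  ## saline leaves the target unchanged
  tr4 <- extend_target_for_reward(target_trajectory(0, 50), 10, "saline")
  expect_equal(target_at(tr4, 13), 50 - 0.8 * 13)
  expect_error(extend_target_for_reward(tr, 5, "alcohol"), "precedes")
})

test_that("reward eligibility is gated at the inclusive 180 mg% limit", {
  expect_true(reward_eligible(160))
  expect_false(reward_eligible(170))
  expect_true(reward_eligible(167))   # 180 exactly: inclusive
  expect_false(reward_eligible(167.1))
  expect_true(reward_eligible(pk_state(c_central = 1.6)))
})

test_that("one alcohol reward raises BrAC by 13 +/- 0.5 mg/dL in 3.0 min", {
  p <- default_pk_params(default_male())
  sim <- simulate_clamp(p, data.frame(t = 0, kind = "alcohol"),
                        t_end = 5, init_brac = 40)
  s <- sim$series
  b <- function(t) s$brac_mg_dl[which.min(abs(s$t_min - t))]
  expect_equal(b(3) - b(0), 13, tolerance = 0.5)
})

test_that("the inter-reward decline tracks -0.8 mg/dL/min after a reward", {
  ## priming-like exposure: four rewards, then a reward-free span
  p <- default_pk_params(default_male())
  rw <- data.frame(t = c(0, 4.2, 8.4, 12.6), kind = "alcohol")
  sim <- simulate_clamp(p, rw, t_end = 24, init_brac = 0)
  s <- sim$series
  w <- s$t_min >= 15.6 & s$t_min <= 20.6
  slope <- coef(lm(brac_mg_dl ~ t_min, s[w, ]))[[2]]
  expect_equal(slope, -0.8, tolerance = 0.05)
})

test_that("all commanded rates stay within the pump range", {
  p <- default_pk_params(default_male())
  rw <- data.frame(t = seq(0, 55, by = 5), kind = "alcohol")
  sim <- simulate_clamp(p, rw, t_end = 60, init_brac = 40)
  expect_true(all(sim$series$infusion_ml_h >= 0))
  expect_true(all(sim$series$infusion_ml_h <= 1998))
})

test_that("with the gate active BrAC never exceeds 180 mg/dL", {
  p <- default_pk_params(default_male())
  ## greedy schedule: a reward attempt every 4 minutes for 2.5 h
  rw <- data.frame(t = seq(0, 146, by = 4), kind = "alcohol")
  sim <- simulate_clamp(p, rw, t_end = 150, init_brac = 40)
  expect_lte(max(sim$series$brac_mg_dl), 180)
  expect_lt(nrow(sim$delivered), nrow(rw))  # the gate actually refused some
})

test_that("tracking error stays small when the target is feasible", {
  p <- default_pk_params(default_male())
  rw <- data.frame(t = seq(0, 55, by = 5), kind = "alcohol")
  sim <- simulate_clamp(p, rw, t_end = 60, init_brac = 40, gate = FALSE)
  err <- abs(sim$series$brac_mg_dl - sim$series$target_mg_dl)
  expect_lt(max(err), 2)
})

test_that("recalibration corrects a mis-estimated elimination rate", {
  prof <- default_male()
  pop <- default_pk_params(prof)
  truth <- pk_params(vd = pop$vd, vmax = pop$vmax * 1.35, km = pop$km,
                     k_per = pop$k_per, f_per = pop$f_per)
  rw <- data.frame(t = seq(0, 115, by = 5), kind = "alcohol")
  run <- function(interval)
    simulate_clamp(truth, rw, t_end = 120, init_brac = 40,
                   ctrl_params = pop, noise_sd = 0, recal_interval = interval)
  with_recal <- run(20)
  without <- run(Inf)
  err <- function(sim) {
    s <- sim$series
    w <- s$t_min >= 100  # end-of-session window
    mean(abs(s$brac_mg_dl[w] - s$target_mg_dl[w]))
  }
  expect_lt(err(with_recal), err(without))
  ## the vmax estimate moved toward the truth
  expect_gt(with_recal$controller$estimate$vmax, pop$vmax)
})

test_that("recalibration updates have the right sign and a fixed point", {
  pop <- default_pk_params(default_male())
  ctrl <- controller_state(pop, model_c_central = 0.8)
  ## reading equal to the model prediction: estimate unchanged
  same <- recalibrate(ctrl, structure(list(t = 20, brac = 80, noise_sd = 0),
                                      class = "brac_reading"))
  expect_equal(same$estimate$vmax, pop$vmax)
  ## reading 10 % above prediction: elimination estimate decreases
  above <- recalibrate(ctrl, structure(list(t = 20, brac = 88, noise_sd = 0),
                                       class = "brac_reading"))
  expect_lt(above$estimate$vmax, pop$vmax)
  ## model state snaps to the reading
  expect_equal(above$model_c_central, 0.88)
})

test_that("saline rewards do not move the BrAC target", {
  p <- default_pk_params(default_male())
  rw <- data.frame(t = 5, kind = "saline")
  sim <- simulate_clamp(p, rw, t_end = 15, init_brac = 50)
  s <- sim$series
  expect_equal(s$target_mg_dl[which.min(abs(s$t_min - 10))], 50 - 0.8 * 10,
               tolerance = 1e-6)
})

test_that("the feedforward law saturates rather than fails", {
  pop <- default_pk_params(default_male())
  ## target far below anything achievable: rate pinned at 0
  ctrl <- controller_state(pop, model_c_central = 1.0, model_c_peripheral = 1.0)
  expect_equal(feedforward_rate(ctrl, 0, 0, 0.05), 0)
  ## target far above: rate pinned at the pump maximum
  expect_equal(feedforward_rate(ctrl, 200, 201, 0.05), 1998)
})
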