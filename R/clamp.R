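#' Prescribed BrAC target trajectory
#'
#' The paradigm prescribes piecewise-linear BrAC dynamics: each alcohol
#' reward ramps the target up by 13 mg/dL over 3.0 min; at all other times
#' the target declines at 0.8 mg/dL/min, clamped at 0. Saline rewards leave
#' the target unchanged.
#'
#' @param t0 start time, minutes.
#' @param value target BrAC at `t0`, mg/dL.
#' @return An object of class `target_trajectory`.
#' @seealso [extend_target_for_reward()], [target_at()]
#' @export
target_trajectory <- function(t0 = 0, value = 0) {
  structure(
    list(bp = data.frame(t = t0, v = value, ramp = FALSE),
         rewards = data.frame(t_start = numeric(0), kind = character(0))),
    class = "target_trajectory"
  )
}

#' Evaluate a target trajectory
#'
#' @param traj a [target_trajectory()].
#' @param t times, minutes (vectorised).
#' @param decline inter-reward decline rate, mg/dL/min.
#' @return Target BrAC in mg/dL at each `t`.
#' @export
target_at <- function(traj, t, decline = .DECLINE_RATE) {
  stopifnot(inherits(traj, "target_trajectory"))
  bp <- traj$bp
  i <- pmax(findInterval(t, bp$t), 1L)
  v <- numeric(length(t))
  ramp <- bp$ramp[i] & i < nrow(bp)
  if (any(ramp)) {
    j <- i[ramp]
    frac <- (t[ramp] - bp$t[j]) / (bp$t[j + 1] - bp$t[j])
    v[ramp] <- bp$v[j] + frac * (bp$v[j + 1] - bp$v[j])
  }
  if (any(!ramp)) {
    j <- i[!ramp]
    v[!ramp] <- pmax(0, bp$v[j] - decline * (t[!ramp] - bp$t[j]))
  }
  v
}

#' Append a reward to a target trajectory
#'
#' An alcohol reward at time `t` appends a +13 mg/dL ramp over 3.0 min,
#' after which the -0.8 mg/dL/min decline resumes; a saline reward leaves
#' the BrAC target unchanged (it is only recorded).
#'
#' @param traj a [target_trajectory()].
#' @param t reward start time, at or after the last breakpoint.
#' @param kind `"alcohol"` or `"saline"`.
#' @return The extended [target_trajectory()].
#' @examples
#' tr <- target_trajectory(0, 50)
#' tr <- extend_target_for_reward(tr, 10, "alcohol")
#' target_at(tr, 13)  # 63: 50 - 0.8*10 = 42 at t = 10, plus 13 over 3 min...
#' @export
extend_target_for_reward <- function(traj, t, kind = c("alcohol", "saline")) {
  stopifnot(inherits(traj, "target_trajectory"))
  kind <- match.arg(kind)
  if (t < max(traj$bp$t)) .stopf("reward time precedes the last breakpoint")
  traj$rewards <- rbind(traj$rewards,
                        data.frame(t_start = t, kind = kind))
  if (kind == "alcohol") {
    v0 <- target_at(traj, t)
    traj$bp <- rbind(traj$bp,
                     data.frame(t = t, v = v0, ramp = TRUE),
                     data.frame(t = t + .REWARD_RAMP_MIN,
                                v = v0 + .REWARD_INCREMENT, ramp = FALSE))
  }
  traj
}

#' Is an alcohol reward currently permitted?
#'
#' The safety gate, checked at work-set start: an alcohol reward may be
#' earned only if the ensuing +13 mg/dL increment cannot push BrAC above
#' the safety limit (inclusive).
#'
#' @param state a [pk_state()] or a numeric BrAC in mg/dL.
#' @param limit safety limit, mg/dL (default 180).
#' @param increment reward increment, mg/dL.
#' @return Logical.
#' @examples
#' reward_eligible(160)  # TRUE  (173 <= 180)
#' reward_eligible(170)  # FALSE (183 > 180)
#' @export
reward_eligible <- function(state, limit = .SAFETY_LIMIT,
                            increment = .REWARD_INCREMENT) {
  if (limit <= 0) .stopf("limit must be positive")
  b <- if (inherits(state, "pk_state")) brac(state) else state
  b + increment <= limit
}

#' Controller state
#'
#' The clamp controller holds its own pharmacokinetic parameter estimate and
#' a model state (its belief about central/peripheral concentrations) that it
#' advances alongside the plant using the rates it actually commands.
#' Periodic breathalyzer readings recalibrate the estimate.
#'
#' @param estimate a [pk_params()] parameter estimate.
#' @param gain dimensionless proportional feedback gain per control step.
#' @param model_c_central,model_c_peripheral initial model concentrations, g/L.
#' @return An object of class `controller_state`.
#' @export
controller_state <- function(estimate, gain = 0.5,
                             model_c_central = 0, model_c_peripheral = 0) {
  stopifnot(inherits(estimate, "pk_params"))
  structure(list(estimate = estimate, gain = gain,
                 model_c_central = model_c_central,
                 model_c_peripheral = model_c_peripheral,
                 last_reading = NULL),
            class = "controller_state")
}

## Pump-clamped model-inversion rate (ml/h). Scalar hot path.
## pe: pk_params estimate; mcc/mcp model concentrations (g/L); targets mg/dL.
.ctrl_rate <- function(mcc, mcp, pe, tgt_now, tgt_next, dt, gain) {
  need <- (tgt_next / 100 - mcc) / dt +
    pe$a * (mcc - mcp) +
    pe$vmax * mcc / ((pe$km + mcc) * pe$v_c) +
    gain * (tgt_now / 100 - mcc) / dt
  rate <- need * pe$v_c / .G_MIN_PER_ML_H
  min(max(rate, 0), .PUMP_MAX_ML_H)
}

#' Model-inversion feedforward rate
#'
#' Computes the pump rate that makes the controller's model BrAC meet the
#' target at `t + dt`, plus a proportional feedback term
#' `gain * (target - model BrAC)`, saturated at 0 and 1998 ml/h.
#'
#' @param ctrl a [controller_state()].
#' @param target_now,target_next target BrAC now and at `t + dt`, mg/dL.
#' @param dt control step, minutes.
#' @return Commanded pump rate, ml/h.
#' @export
feedforward_rate <- function(ctrl, target_now, target_next, dt) {
  stopifnot(inherits(ctrl, "controller_state"))
  .ctrl_rate(ctrl$model_c_central, ctrl$model_c_peripheral, ctrl$estimate,
             target_now, target_next, dt, ctrl$gain)
}

#' Recalibrate the controller from a BrAC reading
#'
#' Multiplicatively rescales the `vmax` estimate by the ratio of predicted
#' to measured BrAC (bounded to +/-30 % per update: a reading above the
#' prediction means less ethanol was eliminated than modelled, so `vmax`
#' decreases) and resets the model central concentration to the reading.
#'
#' @param ctrl a [controller_state()].
#' @param reading a `brac_reading` from [measure_brac()].
#' @return The updated [controller_state()].
#' @export
recalibrate <- function(ctrl, reading) {
  stopifnot(inherits(ctrl, "controller_state"),
            inherits(reading, "brac_reading"))
  if (!is.null(ctrl$last_reading) && reading$t < ctrl$last_reading$t)
    .stopf("readings must arrive in time order")
  pred <- ctrl$model_c_central * 100
  if (reading$brac > 1 && pred > 1) {
    fac <- min(max(pred / reading$brac, 0.7), 1.3)
    est <- ctrl$estimate
    ctrl$estimate <- pk_params(vd = est$vd, vmax = est$vmax * fac,
                               km = est$km, k_per = est$k_per,
                               f_per = est$f_per)
  }
  ctrl$model_c_central <- reading$brac / 100
  ctrl$last_reading <- reading
  ctrl
}

#' Simulate the BrAC clamp under a scripted reward schedule
#'
#' Co-simulates the subject's (true) pharmacokinetics and the clamp
#' controller: at each step the controller commands the pump rate that makes
#' its model track the prescribed target trajectory, the plant is advanced
#' with that rate, and the target is extended whenever a scheduled reward is
#' delivered. Scheduled alcohol rewards are skipped when the safety gate is
#' active and the increment would exceed the limit.
#'
#' @param params true subject [pk_params()].
#' @param rewards data frame with columns `t` (minutes) and `kind`
#'   (`"alcohol"`/`"saline"`); may have zero rows.
#' @param t_end simulation end, minutes.
#' @param t_start simulation start, minutes.
#' @param init_brac initial BrAC, mg/dL; both compartments start equilibrated
#'   at this level.
#' @param start_target initial target BrAC (defaults to `init_brac`).
#' @param ctrl_params controller parameter estimate (defaults to the truth).
#' @param gain controller feedback gain.
#' @param dt integrator/control step, minutes.
#' @param noise_sd breathalyzer noise SD, mg/dL.
#' @param recal_interval minutes between recalibration readings (`Inf` to
#'   disable; readings require `noise_sd >= 0`).
#' @param gate apply the 180 mg/dL safety gate to scheduled alcohol rewards.
#' @param safety_limit gate limit, mg/dL.
#' @param seed optional RNG seed (only used when `noise_sd > 0`).
#' @return A list of class `clamp_sim`: `series` (data frame `t_min`,
#'   `brac_mg_dl`, `target_mg_dl`, `infusion_ml_h`, `kind`), `trajectory`,
#'   `delivered` (rewards actually delivered), `final_state`, `controller`.
#' @export
simulate_clamp <- function(params, rewards = data.frame(t = numeric(0),
                                                        kind = character(0)),
                           t_end, t_start = 0, init_brac = 0,
                           start_target = init_brac,
                           ctrl_params = params, gain = 0.5, dt = 0.05,
                           noise_sd = 0, recal_interval = Inf,
                           gate = TRUE, safety_limit = .SAFETY_LIMIT,
                           seed = NULL) {
  stopifnot(inherits(params, "pk_params"), inherits(ctrl_params, "pk_params"))
  if (!is.null(seed)) set.seed(seed)
  if (nrow(rewards) > 0) rewards <- rewards[order(rewards$t), , drop = FALSE]

  n <- round((t_end - t_start) / dt)
  tt <- t_start + dt * (0:n)
  cc <- init_brac / 100; cp <- cc; el <- 0; inf <- 0
  mcc <- cc; mcp <- cp
  pe <- ctrl_params
  tg <- start_target
  ramp_until <- -Inf
  saline_until <- -Inf
  traj <- target_trajectory(t_start, start_target)
  delivered <- list()
  ridx <- 1L
  next_recal <- t_start + recal_interval
  last_vmax_fac <- 1

  out_b <- numeric(n + 1); out_tg <- numeric(n + 1); out_r <- numeric(n + 1)
  out_b[1] <- cc * 100; out_tg[1] <- tg; out_r[1] <- 0

  for (i in seq_len(n)) {
    t <- tt[i]
    ## deliver scheduled rewards due at/before t
    while (ridx <= nrow(rewards) && rewards$t[ridx] <= t + 1e-9) {
      kind <- rewards$kind[ridx]
      ok <- TRUE
      if (kind == "alcohol" && gate)
        ok <- reward_eligible(cc * 100, limit = safety_limit)
      if (ok) {
        traj <- extend_target_for_reward(traj, t, kind)
        if (kind == "alcohol") {
          tg <- target_at(traj, t)
          ramp_until <- t + .REWARD_RAMP_MIN
        } else saline_until <- t + .REWARD_RAMP_MIN
        delivered[[length(delivered) + 1L]] <-
          data.frame(t = t, kind = kind)
      }
      ridx <- ridx + 1L
    }
    ## target over this step
    tg_next <- if (t < ramp_until - 1e-9)
      tg + .REWARD_INCREMENT / .REWARD_RAMP_MIN * dt
    else max(0, tg - .DECLINE_RATE * dt)
    ## controller command, plant + model update
    rate <- .ctrl_rate(mcc, mcp, pe, tg, tg_next, dt, gain)
    u <- rate * .G_MIN_PER_ML_H
    m <- .pk_rk4(mcc, mcp, 0, pe, u, dt); mcc <- m[1]; mcp <- m[2]
    y <- .pk_rk4(cc, cp, el, params, u, dt)
    cc <- y[1]; cp <- y[2]; el <- y[3]; inf <- inf + u * dt
    tg <- tg_next
    ## periodic breathalyzer recalibration
    if (tt[i + 1] + 1e-9 >= next_recal) {
      st <- pk_state(t = tt[i + 1], c_central = cc, c_peripheral = cp)
      rd <- measure_brac(st, noise_sd)
      ctrl <- controller_state(pe, gain, mcc, mcp)
      ctrl <- recalibrate(ctrl, rd)
      pe <- ctrl$estimate; mcc <- ctrl$model_c_central
      next_recal <- next_recal + recal_interval
    }
    out_b[i + 1] <- cc * 100; out_tg[i + 1] <- tg; out_r[i + 1] <- rate
  }

  series <- data.frame(t_min = tt, brac_mg_dl = out_b, target_mg_dl = out_tg,
                       infusion_ml_h = out_r)
  structure(
    list(series = series,
         trajectory = traj,
         delivered = if (length(delivered)) do.call(rbind, delivered)
                     else data.frame(t = numeric(0), kind = character(0)),
         final_state = pk_state(t = tt[n + 1], c_central = cc,
                                c_peripheral = cp, cumulative_infused = inf,
                                cumulative_eliminated = el),
         controller = controller_state(pe, gain, mcc, mcp)),
    class = "clamp_sim"
  )
}

#' @export
print.clamp_sim <- function(x, ...) {
  s <- x$series
  cat(sprintf(
    "<clamp_sim> %.0f-%.0f min, %d rewards delivered, peak BrAC %.1f mg/dL, max rate %.0f ml/h\n",
    min(s$t_min), max(s$t_min), nrow(x$delivered), max(s$brac_mg_dl),
    max(s$infusion_ml_h)))
  invisible(x)
}
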