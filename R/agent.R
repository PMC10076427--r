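#' Behavioral agent parameters
#'
#' The agent chooses among working for alcohol, working for water (saline),
#' and resting via a softmax over utilities
#' \deqn{u_{alc} = wp + w_+ (1 - \delta L) -
#'   w_{av} \max(0, BrAC - c)/100 + w_- \cdot desire/100 - fatigue \cdot t}
#' with four channels: a drug-attenuated anticipation of the pleasure of
#' the next +13 mg/dL reward (`w_+`, scaled by `1 - \delta L` where
#' `\delta` is the attenuation per ng/ml of blood level `L`); an
#' unattenuated aversion to exceeding the agent's comfort ceiling `c`
#' (`w_av`, reflecting the instruction to seek pleasant and avoid
#' unpleasant alcohol effects); a desire term (`w_-`, the
#' negative-reinforcement channel: desire rises while BrAC falls); and
#' fatigue growing with session time. Working for water shares the
#' baseline work propensity; resting has utility 0. The equilibrium
#' exposure - where working and resting break even - falls as `\delta L`
#' rises, which is how the drug lowers cumulative work.
#'
#' Subjective state follows linear-gain dynamics with exponential return to
#' baseline and slope-asymmetric gains: stimulation and wellbeing rise with
#' BrAC level and rising BrAC (attenuated by the drug), desire rises while
#' BrAC falls, sedation and drunkenness track the BrAC level.
#'
#' @param work_propensity baseline utility of working (between-subject
#'   random effect in cohort simulations).
#' @param water_bonus additive utility offset for working for water.
#' @param pos_weight utility weight on the anticipated pleasure of a reward.
#' @param av_weight utility weight on the aversion of exceeding the comfort
#'   ceiling (per 100 mg/dL of overshoot).
#' @param neg_weight utility weight on desire (negative-reinforcement
#'   channel).
#' @param drug_attenuation attenuation of positive reinforcement per ng/ml
#'   of drug blood level (`delta`); `delta * level` is capped below 1.
#' @param attenuate_negative also attenuate the desire-driven
#'   (negative-reinforcement) term by the drug; off by default.
#' @param fatigue_rate utility decay of working per hour of session time.
#' @param temperature softmax decision noise; 0 reduces to argmax.
#' @param latency_mean_s pause before each decision, seconds.
#' @param brac_ceiling comfort ceiling, mg/dL: BrAC above which further
#'   exposure becomes aversive.
#' @param stim_base,stim_gain,stim_lvl,stim_decay stimulation dynamics:
#'   baseline, gain per (mg/dL/min) of rising BrAC, gain per mg/dL of level,
#'   return-to-baseline rate per min.
#' @param well_base,well_gain,well_lvl,well_decay wellbeing dynamics.
#' @param desire_base,desire_gain,desire_decay desire dynamics (gain per
#'   (mg/dL/min) of falling BrAC).
#' @param desire_gap desire gain per mg/dL of sustained drop below the
#'   recent-peak BrAC reference (the "unintended drop" signal: brief
#'   inter-reward sawtooth dips barely move it, the long decline of the
#'   futile phase does).
#' @param gap_floor perception threshold of the drop signal, mg/dL: dips
#'   smaller than this do not register.
#' @param gap_sat saturation of the drop signal, mg/dL: drops this far
#'   beyond the threshold do not raise desire further.
#' @param peak_decay forgetting rate of the recent-peak reference, 1/min
#'   (0 = the session peak is never forgotten).
#' @param sed_lvl,sed_decay sedation: equilibrium `sed_lvl * BrAC`, rate.
#' @param drunk_lvl,drunk_decay drunkenness dynamics.
#' @return An object of class `asa_agent`.
#' @export
agent_params <- function(work_propensity = -1.6, water_bonus = 1.0,
                         pos_weight = 1.5, av_weight = 3, neg_weight = 4,
                         drug_attenuation = 0, attenuate_negative = FALSE,
                         fatigue_rate = 0.25, temperature = 0.8,
                         latency_mean_s = 4, brac_ceiling = 85,
                         stim_base = 20, stim_gain = 0.3, stim_lvl = 0.02,
                         stim_decay = 0.08,
                         well_base = 50, well_gain = 0.35, well_lvl = 0.006,
                         well_decay = 0.08,
                         desire_base = 30, desire_gain = 0.2,
                         desire_gap = 0.02, gap_floor = 0, gap_sat = 15,
                         peak_decay = 0,
                         desire_decay = 0.03,
                         sed_lvl = 0.4, sed_decay = 0.05,
                         drunk_lvl = 0.6, drunk_decay = 0.05) {
  if (temperature < 0) .stopf("temperature must be nonnegative")
  if (drug_attenuation < 0) .stopf("drug_attenuation must be nonnegative")
  if (brac_ceiling <= 0) .stopf("brac_ceiling must be positive")
  structure(as.list(environment()), class = "asa_agent")
}

#' @export
print.asa_agent <- function(x, ...) {
  cat(sprintf(
    "<asa_agent> propensity %.2f, pos %.2f, neg %.2f, delta %.4f, temp %.2f\n",
    x$work_propensity, x$pos_weight, x$neg_weight, x$drug_attenuation,
    x$temperature))
  invisible(x)
}

#' Subjective (visual-analog) state
#'
#' Five 0-100 visual-analog scales carried by the agent.
#'
#' @param stimulation,sedation,wellbeing,desire,drunkenness initial values.
#' @return An object of class `subjective_state`.
#' @export
subjective_state <- function(stimulation = 20, sedation = 10, wellbeing = 50,
                             desire = 30, drunkenness = 0) {
  v <- c(stimulation = stimulation, sedation = sedation,
         wellbeing = wellbeing, desire = desire, drunkenness = drunkenness)
  if (any(v < 0 | v > 100)) .stopf("VAS values must lie in [0, 100]")
  structure(as.list(v), class = "subjective_state")
}

## drug attenuation factor, capped so the attenuated weight stays >= 0
.att <- function(delta, level) max(0, 1 - delta * level)

#' Update the subjective state
#'
#' Advances the visual-analog dynamics over `dt` minutes at the given BrAC
#' level and slope. Stimulation and wellbeing gains (level and positive
#' slope) are scaled by `1 - delta * drug_level`; desire rises while BrAC
#' falls. All scales are clipped to `[0, 100]`.
#'
#' @param state a [subjective_state()].
#' @param params an [agent_params()].
#' @param brac current BrAC, mg/dL.
#' @param brac_slope current BrAC slope, mg/dL/min.
#' @param drug_level drug blood level, ng/ml.
#' @param dt update interval, minutes.
#' @return The updated [subjective_state()].
#' @export
update_subjective <- function(state, params, brac, brac_slope,
                              drug_level = 0, dt = 1) {
  stopifnot(inherits(state, "subjective_state"),
            inherits(params, "asa_agent"))
  if (!all(is.finite(c(brac, brac_slope)))) .stopf("inputs must be finite")
  p <- params
  att <- .att(p$drug_attenuation, drug_level)
  up <- max(brac_slope, 0)
  dn <- max(-brac_slope, 0)
  clip <- function(x) min(100, max(0, x))
  state$stimulation <- clip(state$stimulation + dt * (
    p$stim_decay * (p$stim_base - state$stimulation) +
      (p$stim_gain * up + p$stim_lvl * brac) * att))
  state$wellbeing <- clip(state$wellbeing + dt * (
    p$well_decay * (p$well_base - state$wellbeing) +
      (p$well_gain * up + p$well_lvl * brac) * att))
  ## recent-peak reference: rises instantly with BrAC, forgets slowly, so
  ## (peak - brac) measures the sustained (not sawtooth) drop
  pk <- state$.brac_peak
  if (is.null(pk)) pk <- brac
  pk <- max(brac, pk - p$peak_decay * (pk - brac) * dt)
  ## thresholded, saturating response: dips smaller than gap_floor (the
  ## inter-reward sawtooth) are not perceived as an unintended decline;
  ## once the drop is clearly felt, feeling still further from the peak
  ## does not keep raising desire proportionally
  gap <- min(max(0, pk - brac - p$gap_floor), p$gap_sat)
  state$.brac_peak <- pk
  state$desire <- clip(state$desire + dt * (
    p$desire_decay * (p$desire_base - state$desire) +
      p$desire_gain * dn + p$desire_gap * gap))
  state$sedation <- clip(state$sedation +
    dt * p$sed_decay * (p$sed_lvl * brac - state$sedation))
  state$drunkenness <- clip(state$drunkenness +
    dt * p$drunk_decay * (p$drunk_lvl * brac - state$drunkenness))
  state
}

#' Choose the next action
#'
#' Softmax (or argmax at temperature 0) over the utilities of
#' `work_alcohol`, `work_water` and `rest`; an ineligible alcohol reward
#' removes that action. Scripted agents override this with their fixed
#' policy. Uses the current RNG stream.
#'
#' @param agent an [agent_params()] or [scripted_agent()].
#' @param state a [subjective_state()].
#' @param context list with `t_min` (session time, minutes of voluntary
#'   work), `brac` (mg/dL), `eligible_alcohol` (logical), `drug_level`
#'   (ng/ml), and `n_started` (work-sets started so far, used by the
#'   alternating scripted policy).
#' @return One of `"work_alcohol"`, `"work_water"`, `"rest"`.
#' @export
decide_action <- function(agent, state, context) UseMethod("decide_action")

#' @export
decide_action.asa_agent <- function(agent, state, context) {
  p <- agent
  att <- .att(p$drug_attenuation, context$drug_level %||% 0)
  att_neg <- if (isTRUE(p$attenuate_negative)) att else 1
  ## the drug blunts the anticipated pleasure of the next reward; the
  ## aversion of exceeding the comfort level is a separate, unattenuated
  ## channel (overshoot discomfort is not an opioid-mediated reward)
  aversion <- p$av_weight * max(0, context$brac - p$brac_ceiling) / 100
  fatigue <- p$fatigue_rate * max(context$t_min, 0) / 60
  u <- c(
    work_alcohol = p$work_propensity + p$pos_weight * att - aversion +
      p$neg_weight * (state$desire / 100) * att_neg - fatigue,
    work_water = p$work_propensity + p$water_bonus - fatigue,
    rest = 0
  )
  if (!isTRUE(context$eligible_alcohol)) u <- u[-1]
  if (p$temperature == 0) return(names(u)[which.max(u)])
  w <- exp((u - max(u)) / p$temperature)
  names(u)[sample.int(length(u), 1, prob = w)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scripted deterministic agents
#'
#' Fixture agents that ignore the subjective state and emit a fixed policy
#' with zero decision latency: `"always_alcohol"` always works for alcohol
#' (resting while ineligible), `"never_work"` always rests, `"alternating"`
#' alternates between alcohol and water work-sets.
#'
#' @param policy one of `"always_alcohol"`, `"never_work"`, `"alternating"`.
#' @return An object of class `c("scripted_agent", "asa_agent")`.
#' @export
scripted_agent <- function(policy = c("always_alcohol", "never_work",
                                      "alternating")) {
  policy <- match.arg(policy)
  a <- agent_params(latency_mean_s = 0, temperature = 0)
  a$policy <- policy
  class(a) <- c("scripted_agent", class(a))
  a
}

#' @export
decide_action.scripted_agent <- function(agent, state, context) {
  switch(agent$policy,
    always_alcohol = if (isTRUE(context$eligible_alcohol)) "work_alcohol"
                     else "rest",
    never_work = "rest",
    alternating = {
      want <- if ((context$n_started %||% 0) %% 2 == 0) "work_alcohol"
              else "work_water"
      if (want == "work_alcohol" && !isTRUE(context$eligible_alcohol)) "rest"
      else want
    })
}
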