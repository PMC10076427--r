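#' Session configuration
#'
#' Structure of one laboratory session on the analytical time axis
#' (`T = 0` at the start of the voluntary work-for-reward phase): a priming
#' interval starting at `T = -wait_until_min` with prompted work-sets
#' (2 saline then 4 alcohol, fixed 4-trial requirement, excluded from the
#' progressive-ratio progression and from cumulative work), a waiting period
#' until `T = 0`, then 150 min of voluntary work.
#'
#' @param priming_saline,priming_alcohol number of prompted saline/alcohol
#'   work-sets.
#' @param priming_trials fixed trial requirement of prompted sets.
#' @param prompt_latency_min pause before each prompted set, minutes.
#' @param wait_until_min priming + waiting span before `T = 0`, minutes.
#' @param vwr_duration_min duration of the voluntary phase, minutes.
#' @param safety_limit BrAC safety gate, mg/dL (inclusive, checked at
#'   work-set start).
#' @param assessment_times subjective assessment times on the `T` axis:
#'   baseline, priming, ascending phase, end.
#' @param brac_noise_sd breathalyzer noise SD, mg/dL.
#' @param recal_interval_min minutes between controller recalibrations.
#' @param rest_min duration of one rest bout, minutes.
#' @param dt integrator/control step, minutes.
#' @param record_interval_min BrAC series recording interval, minutes.
#' @param subjective_dt_min subjective-state update interval, minutes.
#' @return An object of class `session_config`.
#' @export
session_config <- function(priming_saline = 2, priming_alcohol = 4,
                           priming_trials = 4, prompt_latency_min = 0.3,
                           wait_until_min = 25, vwr_duration_min = 150,
                           safety_limit = .SAFETY_LIMIT,
                           assessment_times = c(-25, 15, 75, 150),
                           brac_noise_sd = 2, recal_interval_min = 20,
                           rest_min = 2, dt = 0.05,
                           record_interval_min = 0.5,
                           subjective_dt_min = 1) {
  if (vwr_duration_min <= 0) .stopf("vwr_duration_min must be positive")
  if (dt <= 0) .stopf("dt must be positive")
  if (any(assessment_times < -wait_until_min |
            assessment_times > vwr_duration_min))
    .stopf("assessment times must lie within the session")
  structure(as.list(environment()), class = "session_config")
}

## event codes kept as plain strings; buffer grows geometrically
.ev_buffer <- function(n = 4096) {
  new.env(parent = emptyenv()) -> e
  e$t <- numeric(n); e$kind <- character(n); e$reward <- character(n)
  e$set_index <- integer(n); e$priming <- logical(n); e$n <- 0L
  e
}
.ev_push <- function(e, t, kind, reward = "none", set_index = NA_integer_,
                     priming = FALSE) {
  i <- e$n + 1L
  if (i > length(e$t)) {
    m <- length(e$t) * 2L
    length(e$t) <- m; length(e$kind) <- m; length(e$reward) <- m
    length(e$set_index) <- m; length(e$priming) <- m
  }
  e$t[i] <- t; e$kind[i] <- kind; e$reward[i] <- reward
  e$set_index[i] <- set_index; e$priming[i] <- priming
  e$n <- i
  invisible(e)
}

#' Run one self-administration session
#'
#' Executes a full session: priming, waiting period, and the voluntary
#' work-for-reward phase, co-simulating the subject's pharmacokinetics, the
#' clamp controller, the adaptive attention task and the behavioral agent.
#' Work-set starts are gated at the safety limit; completed sets trigger a
#' +13 mg/dL alcohol ramp or a 15-ml saline push; the alcohol and saline
#' progressive-ratio progressions advance independently. Event times are
#' exact (not quantized to the integrator grid).
#'
#' @param profile a [subject_profile()].
#' @param pk true subject [pk_params()] (defaults to
#'   [default_pk_params()]).
#' @param agent an [agent_params()] or [scripted_agent()].
#' @param schedule a [work_schedule()].
#' @param cat a [cat_config()].
#' @param config a [session_config()].
#' @param ctrl_params the controller's parameter estimate; defaults to the
#'   population model for the profile (i.e. [default_pk_params()]), so a
#'   perturbed `pk` exercises the recalibration path.
#' @param drug_level drug blood level, ng/ml (0 = placebo/baseline).
#' @param session_index 1 (baseline) or 2 (on medication).
#' @param seed optional RNG seed; identical seeds replay bit-identically.
#' @return An object of class `asa_session` with fields `events`
#'   (data frame: `t`, `kind`, `reward_kind`, `set_index`, `priming`),
#'   `brac` (data frame: `t_min`, `brac_mg_dl`, `target_mg_dl`,
#'   `infusion_ml_h`), `assessments`, `cwfa`, `cwfs`, `peak_brac`,
#'   `mean_brac`, and metadata.
#' @export
run_session <- function(profile, pk = default_pk_params(profile),
                        agent = agent_params(),
                        schedule = calibrate_schedule(),
                        cat = cat_config(), config = session_config(),
                        ctrl_params = NULL, drug_level = 0,
                        session_index = 1, seed = NULL) {
  stopifnot(inherits(profile, "subject_profile"), inherits(pk, "pk_params"),
            inherits(agent, "asa_agent"),
            inherits(schedule, "work_schedule"),
            inherits(cat, "cat_config"), inherits(config, "session_config"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ctrl_params)) ctrl_params <- default_pk_params(profile)

  cfg <- config
  dt <- cfg$dt
  t0 <- -cfg$wait_until_min
  t_end <- cfg$vwr_duration_min
  n <- round((t_end - t0) / dt)
  tt <- t0 + dt * (0:n)

  ## plant + controller; parameters hoisted to scalars for the hot loop
  cc <- 0; cp <- 0; el <- 0; inf <- 0
  mcc <- 0; mcp <- 0
  pe <- ctrl_params
  gain <- 0.5
  p_vc <- pk$v_c; p_a <- pk$a; p_b <- pk$b; p_vm <- pk$vmax; p_km <- pk$km
  e_vc <- pe$v_c; e_a <- pe$a; e_b <- pe$b; e_vm <- pe$vmax; e_km <- pe$km
  ramp_slope <- .REWARD_INCREMENT / .REWARD_RAMP_MIN * dt
  decl_step <- .DECLINE_RATE * dt
  gpm <- .G_MIN_PER_ML_H
  traj <- target_trajectory(t0, 0)
  ramp_until <- -Inf
  saline_until <- -Inf
  next_recal <- t0 + cfg$recal_interval_min

  ## task + agent
  window <- cat$window_init_s
  subj <- subjective_state()
  ev <- .ev_buffer()
  priming_queue <- c(rep("saline", cfg$priming_saline),
                     rep("alcohol", cfg$priming_alcohol))
  prim_i <- 0L
  k_alc <- 0L; k_sal <- 0L       # completed VWR progression counts
  n_started <- 0L                # VWR work-sets started (for alternation)
  mode <- "latency"              # latency | working | reward | rest | wait
  next_t <- t0 + cfg$prompt_latency_min
  set_kind <- ""; set_req <- 0L; set_done <- 0L; set_idx <- 0L
  in_priming <- TRUE

  ## recording
  rec_every <- max(1L, round(cfg$record_interval_min / dt))
  n_rec <- length(seq(0, n, by = rec_every))
  rec_t <- numeric(n_rec); out_b <- numeric(n_rec)
  out_tg <- numeric(n_rec); out_r <- numeric(n_rec)
  out_s <- numeric(n_rec); ri <- 1L
  rec_t[1] <- t0; out_b[1] <- 0; out_tg[1] <- 0; out_r[1] <- 0; out_s[1] <- 0
  tg <- 0; sal_total <- 0
  assess <- cfg$assessment_times[order(cfg$assessment_times)]
  na_done <- 0L
  assess_rows <- vector("list", length(assess))
  prev_brac_min <- 0; next_subj <- t0 + cfg$subjective_dt_min

  start_workset <- function(kind, t) {
    if (in_priming) {
      set_idx <<- prim_i
      set_req <<- cfg$priming_trials
    } else {
      set_idx <<- (if (kind == "alcohol") k_alc else k_sal) + 1L
      set_req <<- required_trials(schedule, set_idx)
      n_started <<- n_started + 1L
    }
    set_kind <<- kind; set_done <<- 0L
    .ev_push(ev, t, "workset_start", kind, set_idx, in_priming)
    mode <<- "working"
    trial <- run_cat_trial(cat, window, 1 + cat$impair_per_mg_dl * cc * 100)
    pending_trial <<- trial
    next_t <<- t + trial$duration_s / 60
  }
  pending_trial <- NULL

  decide_and_go <- function(t) {
    elig <- reward_eligible(cc * 100, limit = cfg$safety_limit)
    act <- decide_action(agent, subj,
                         list(t_min = t, brac = cc * 100,
                              eligible_alcohol = elig,
                              drug_level = drug_level,
                              n_started = n_started))
    if (act == "rest") {
      .ev_push(ev, t, "rest_start")
      mode <<- "rest"
      next_t <<- t + cfg$rest_min
    } else {
      start_workset(if (act == "work_alcohol") "alcohol" else "saline", t)
    }
  }

  for (i in seq_len(n)) {
    t <- tt[i]

    ## resolve discrete events due within this step (exact times)
    while (next_t <= t + dt - 1e-9) {
      te <- next_t
      if (mode == "latency") {
        if (in_priming) {
          prim_i <- prim_i + 1L
          start_workset(priming_queue[prim_i], te)
        } else decide_and_go(te)
      } else if (mode == "working") {
        tr <- pending_trial
        .ev_push(ev, te, if (tr$success) "trial_success" else "trial_fail",
                 set_kind, set_idx, in_priming)
        window <- adapt_window(cat, window, tr$success)
        if (tr$success) set_done <- set_done + 1L
        if (set_done >= set_req) {
          .ev_push(ev, te, "workset_complete", set_kind, set_idx, in_priming)
          if (!in_priming) {
            if (set_kind == "alcohol") k_alc <- k_alc + 1L
            else k_sal <- k_sal + 1L
          }
          .ev_push(ev, te, "reward_start", set_kind, set_idx, in_priming)
          traj <- extend_target_for_reward(traj, te, set_kind)
          if (set_kind == "alcohol") ramp_until <- te + .REWARD_RAMP_MIN
          else saline_until <- te + .REWARD_RAMP_MIN
          mode <- "reward"
          next_t <- te + .REWARD_RAMP_MIN
        } else {
          trial <- run_cat_trial(cat, window,
                                 1 + cat$impair_per_mg_dl * cc * 100)
          pending_trial <- trial
          next_t <- te + trial$duration_s / 60
        }
      } else if (mode == "reward") {
        .ev_push(ev, te, "reward_end", set_kind, set_idx, in_priming)
        if (in_priming && prim_i >= length(priming_queue)) {
          in_priming <- FALSE
          mode <- "wait"
          next_t <- max(0, te)
        } else {
          mode <- "latency"
          next_t <- te + if (in_priming) cfg$prompt_latency_min
                         else agent$latency_mean_s / 60
        }
      } else if (mode == "rest") {
        .ev_push(ev, te, "rest_end")
        mode <- "latency"
        next_t <- te + agent$latency_mean_s / 60
      } else if (mode == "wait") {
        ## voluntary phase begins
        mode <- "latency"
        next_t <- te + agent$latency_mean_s / 60
      }
    }

    ## clamp control + pharmacokinetics on the grid; the target is tracked
    ## incrementally (ramp slope +13/3 during a reward, -0.8 otherwise);
    ## controller inversion and both RK4 updates are inlined for speed
    tg_next <- if (t < ramp_until - 1e-9) tg + ramp_slope
               else max(0, tg - decl_step)
    need <- (tg_next / 100 - mcc) / dt + e_a * (mcc - mcp) +
      e_vm * mcc / ((e_km + mcc) * e_vc) + gain * (tg / 100 - mcc) / dt
    rate <- need * e_vc / gpm
    rate <- if (rate < 0) 0 else if (rate > .PUMP_MAX_ML_H) .PUMP_MAX_ML_H
            else rate
    u <- rate * gpm
    {  # controller model step (RK4)
      w1 <- (u - e_vm * mcc / (e_km + mcc)) / e_vc - e_a * (mcc - mcp)
      x1 <- e_b * (mcc - mcp)
      c2 <- mcc + 0.5 * dt * w1; q2 <- mcp + 0.5 * dt * x1
      w2 <- (u - e_vm * c2 / (e_km + c2)) / e_vc - e_a * (c2 - q2)
      x2 <- e_b * (c2 - q2)
      c3 <- mcc + 0.5 * dt * w2; q3 <- mcp + 0.5 * dt * x2
      w3 <- (u - e_vm * c3 / (e_km + c3)) / e_vc - e_a * (c3 - q3)
      x3 <- e_b * (c3 - q3)
      c4 <- mcc + dt * w3; q4 <- mcp + dt * x3
      w4 <- (u - e_vm * c4 / (e_km + c4)) / e_vc - e_a * (c4 - q4)
      x4 <- e_b * (c4 - q4)
      mcc <- mcc + dt * (w1 + 2 * w2 + 2 * w3 + w4) / 6
      mcp <- mcp + dt * (x1 + 2 * x2 + 2 * x3 + x4) / 6
      if (mcc < 0) mcc <- 0
      if (mcp < 0) mcp <- 0
    }
    {  # plant step (RK4) with eliminated-mass co-integration
      g1 <- p_vm * cc / (p_km + cc)
      w1 <- (u - g1) / p_vc - p_a * (cc - cp); x1 <- p_b * (cc - cp)
      c2 <- cc + 0.5 * dt * w1; q2 <- cp + 0.5 * dt * x1
      g2 <- p_vm * c2 / (p_km + c2)
      w2 <- (u - g2) / p_vc - p_a * (c2 - q2); x2 <- p_b * (c2 - q2)
      c3 <- cc + 0.5 * dt * w2; q3 <- cp + 0.5 * dt * x2
      g3 <- p_vm * c3 / (p_km + c3)
      w3 <- (u - g3) / p_vc - p_a * (c3 - q3); x3 <- p_b * (c3 - q3)
      c4 <- cc + dt * w3; q4 <- cp + dt * x3
      g4 <- p_vm * c4 / (p_km + c4)
      w4 <- (u - g4) / p_vc - p_a * (c4 - q4); x4 <- p_b * (c4 - q4)
      cc <- cc + dt * (w1 + 2 * w2 + 2 * w3 + w4) / 6
      cp <- cp + dt * (x1 + 2 * x2 + 2 * x3 + x4) / 6
      if (cc < 0) cc <- 0
      if (cp < 0) cp <- 0
      el <- el + dt * (g1 + 2 * g2 + 2 * g3 + g4) / 6
      inf <- inf + u * dt
    }
    tg <- tg_next
    sal_rate <- if (t < saline_until - 1e-9) .SALINE_RATE_ML_MIN else 0
    sal_total <- sal_total + sal_rate * dt

    ## breathalyzer recalibration
    if (tt[i + 1] + 1e-9 >= next_recal) {
      st <- pk_state(t = tt[i + 1], c_central = cc, c_peripheral = cp)
      rd <- measure_brac(st, cfg$brac_noise_sd)
      .ev_push(ev, tt[i + 1], "brac_reading")
      ctrl <- recalibrate(controller_state(pe, gain, mcc, mcp), rd)
      pe <- ctrl$estimate; mcc <- ctrl$model_c_central
      e_vm <- pe$vmax
      next_recal <- next_recal + cfg$recal_interval_min
    }

    ## subjective dynamics (1-min cadence)
    if (tt[i + 1] + 1e-9 >= next_subj) {
      slope <- (cc * 100 - prev_brac_min) / cfg$subjective_dt_min
      subj <- update_subjective(subj, agent, cc * 100, slope, drug_level,
                                cfg$subjective_dt_min)
      prev_brac_min <- cc * 100
      next_subj <- next_subj + cfg$subjective_dt_min
    }

    ## assessments
    while (na_done < length(assess) && tt[i + 1] + 1e-9 >= assess[na_done + 1]) {
      na_done <- na_done + 1L
      .ev_push(ev, assess[na_done], "assessment")
      assess_rows[[na_done]] <- data.frame(
        t = assess[na_done], stimulation = subj$stimulation,
        sedation = subj$sedation, wellbeing = subj$wellbeing,
        desire = subj$desire, drunkenness = subj$drunkenness)
    }

    ## recording
    if (i %% rec_every == 0L) {
      ri <- ri + 1L
      rec_t[ri] <- tt[i + 1]
      out_b[ri] <- cc * 100; out_tg[ri] <- tg; out_r[ri] <- rate
      out_s[ri] <- sal_rate
    }
  }

  ## handle a baseline assessment exactly at t0 (before the loop advances)
  if (length(assess) && assess[1] <= t0 && is.null(assess_rows[[1]])) {
    assess_rows[[1]] <- data.frame(
      t = assess[1], stimulation = subj$stimulation, sedation = subj$sedation,
      wellbeing = subj$wellbeing, desire = subj$desire,
      drunkenness = subj$drunkenness)
  }

  ne <- ev$n
  events <- data.frame(t = ev$t[seq_len(ne)], kind = ev$kind[seq_len(ne)],
                       reward_kind = ev$reward[seq_len(ne)],
                       set_index = ev$set_index[seq_len(ne)],
                       priming = ev$priming[seq_len(ne)])
  brac_series <- data.frame(t_min = rec_t[seq_len(ri)],
                            brac_mg_dl = out_b[seq_len(ri)],
                            target_mg_dl = out_tg[seq_len(ri)],
                            infusion_ml_h = out_r[seq_len(ri)],
                            saline_ml_min = out_s[seq_len(ri)])
  vwr <- brac_series$t_min >= 0
  res <- structure(
    list(subject = profile$id, session_index = session_index,
         events = events, brac = brac_series,
         assessments = do.call(rbind, assess_rows),
         trajectory = traj, schedule = schedule,
         drug_level = drug_level, seed = seed,
         saline_ml_total = sal_total,
         peak_brac = max(brac_series$brac_mg_dl[vwr]),
         mean_brac = mean(brac_series$brac_mg_dl[vwr]),
         final_state = pk_state(t = t_end, c_central = cc, c_peripheral = cp,
                                cumulative_infused = inf,
                                cumulative_eliminated = el)),
    class = "asa_session")
  res$cwfa <- cumulative_work(res, "alcohol")
  res$cwfs <- cumulative_work(res, "saline")
  res
}

#' Cumulative work in a session window
#'
#' Counts the correct attention-task trials performed toward a reward kind
#' with event time in `[window[1], window[2])` of the voluntary phase
#' (`T = 0` origin). Trials of incomplete work-sets count; prompted priming
#' trials never do.
#'
#' @param session an [run_session()] result.
#' @param kind `"alcohol"` or `"saline"`.
#' @param window half-open time window `[t0, t1)` in minutes, inside
#'   `[0, 150]`.
#' @return Integer trial count.
#' @examples
#' \donttest{
#' s <- run_session(subject_profile("s", "male", 30, 180, 80), seed = 1)
#' cumulative_work(s, "alcohol") ==
#'   cumulative_work(s, "alcohol", c(0, 75)) +
#'   cumulative_work(s, "alcohol", c(75, 150))
#' }
#' @export
cumulative_work <- function(session, kind = c("alcohol", "saline"),
                            window = c(0, 150)) {
  stopifnot(inherits(session, "asa_session"))
  kind <- match.arg(kind)
  if (window[1] < 0 || window[2] > 150 + 1e-9 || window[2] < window[1])
    .stopf("window must lie within [0, 150]")
  e <- session$events
  sum(e$kind == "trial_success" & e$reward_kind == kind & !e$priming &
        e$t >= window[1] & e$t < window[2])
}

#' @export
print.asa_session <- function(x, ...) {
  cat(sprintf(
    "<asa_session> subject %s, session %d%s\n", x$subject, x$session_index,
    if (x$drug_level > 0) sprintf(" (drug level %.1f ng/ml)", x$drug_level)
    else ""))
  cat(sprintf("  cWFA %d, cWFS %d, peak BrAC %.1f, mean BrAC %.1f mg/dL\n",
              x$cwfa, x$cwfs, x$peak_brac, x$mean_brac))
  invisible(x)
}

#' @export
summary.asa_session <- function(object, ...) {
  x <- object
  e <- x$events
  vwr <- !e$priming & e$t >= 0
  out <- list(
    subject = x$subject, session_index = x$session_index,
    cwfa = x$cwfa, cwfs = x$cwfs,
    cwfa_ascending = cumulative_work(x, "alcohol", c(0, 75)),
    cwfa_plateau = cumulative_work(x, "alcohol", c(75, 150)),
    peak_brac = x$peak_brac, mean_brac = x$mean_brac,
    worksets_alcohol = sum(e$kind == "workset_complete" &
                             e$reward_kind == "alcohol" & vwr),
    worksets_saline = sum(e$kind == "workset_complete" &
                            e$reward_kind == "saline" & vwr),
    rewards = sum(e$kind == "reward_start" & vwr))
  class(out) <- "summary.asa_session"
  out
}

#' @export
print.summary.asa_session <- function(x, ...) {
  cat(sprintf("Session %d of subject %s\n", x$session_index, x$subject))
  cat(sprintf("  cWFA %d (ascending %d, plateau %d), cWFS %d\n",
              x$cwfa, x$cwfa_ascending, x$cwfa_plateau, x$cwfs))
  cat(sprintf("  completed work-sets: %d alcohol, %d saline\n",
              x$worksets_alcohol, x$worksets_saline))
  cat(sprintf("  peak BrAC %.1f mg/dL, mean BrAC %.1f mg/dL\n",
              x$peak_brac, x$mean_brac))
  invisible(x)
}

#' Plot a session
#'
#' BrAC and target trajectories over session time, with reward deliveries
#' marked.
#'
#' @param x an `asa_session`.
#' @param ... passed to [plot()].
#' @export
plot.asa_session <- function(x, ...) {
  s <- x$brac
  graphics::plot(s$t_min, s$brac_mg_dl, type = "l", lwd = 1.5,
                 xlab = "time (min, T = 0 at voluntary work start)",
                 ylab = "BrAC (mg/dL)", ...)
  graphics::lines(s$t_min, s$target_mg_dl, lty = 2, col = "grey50")
  rw <- x$events[x$events$kind == "reward_start", ]
  if (nrow(rw)) {
    graphics::points(rw$t, rep(0, nrow(rw)),
                     pch = ifelse(rw$reward_kind == "alcohol", 17, 2),
                     col = ifelse(rw$reward_kind == "alcohol", "firebrick",
                                  "steelblue"))
  }
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}
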