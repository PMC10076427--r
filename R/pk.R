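#' Convert an infusate pump rate to an ethanol mass rate
#'
#' The infusate is a 6.0 % (v/v) ethanol solution in 0.9 % saline; the pump
#' delivers at most 1998 ml/h. With ethanol density 0.7893 g/ml, the mass
#' rate is `rate * 0.06 * 0.7893 / 60` g/min.
#'
#' @param rate_ml_h pump rate in ml/h, within `[0, 1998]`.
#' @return Ethanol mass rate in g/min.
#' @examples
#' ethanol_mass_rate(1998)  # 1.577 g/min
#' @export
ethanol_mass_rate <- function(rate_ml_h) {
  if (!is.numeric(rate_ml_h) || any(!is.finite(rate_ml_h)))
    .stopf("rate_ml_h must be finite numeric")
  if (any(rate_ml_h < 0 | rate_ml_h > .PUMP_MAX_ML_H))
    .stopf("pump rate outside [0, %d] ml/h", .PUMP_MAX_ML_H)
  rate_ml_h * .G_MIN_PER_ML_H
}

#' Pharmacokinetic state of one subject
#'
#' @param t time, minutes.
#' @param c_central central (arterial-equivalent) concentration, g/L.
#' @param c_peripheral peripheral concentration, g/L.
#' @param cumulative_infused grams of ethanol infused so far.
#' @param cumulative_eliminated grams eliminated so far.
#' @return An object of class `pk_state`.
#' @export
pk_state <- function(t = 0, c_central = 0, c_peripheral = 0,
                     cumulative_infused = 0, cumulative_eliminated = 0) {
  if (c_central < 0 || c_peripheral < 0)
    .stopf("concentrations must be nonnegative")
  structure(
    list(t = t, c_central = c_central, c_peripheral = c_peripheral,
         cumulative_infused = cumulative_infused,
         cumulative_eliminated = cumulative_eliminated),
    class = "pk_state"
  )
}

#' @export
print.pk_state <- function(x, ...) {
  cat(sprintf(
    "<pk_state> t %.2f min, BrAC %.1f mg/dL (central %.3f, peripheral %.3f g/L)\n",
    x$t, brac(x), x$c_central, x$c_peripheral))
  invisible(x)
}

#' Breath alcohol concentration of a state
#'
#' BrAC in mg/dL is the central concentration in g/L times 100 ("mg%" is an
#' exact synonym of mg/dL).
#'
#' @param state a [pk_state()].
#' @return BrAC in mg/dL.
#' @export
brac <- function(state) state$c_central * 100

## One fixed-step RK4 update of (c_central, c_peripheral, eliminated).
## Scalar hot path shared by the session engine; p is a pk_params list with
## precomputed v_c, a, b. u is the ethanol mass input in g/min.
.pk_rk4 <- function(cc, cp, el, p, u, dt) {
  vc <- p$v_c; a <- p$a; b <- p$b; vm <- p$vmax; km <- p$km
  e1 <- vm * cc / (km + cc)
  k1c <- (u - e1) / vc - a * (cc - cp); k1p <- b * (cc - cp)
  cc2 <- cc + 0.5 * dt * k1c; cp2 <- cp + 0.5 * dt * k1p
  e2 <- vm * cc2 / (km + cc2)
  k2c <- (u - e2) / vc - a * (cc2 - cp2); k2p <- b * (cc2 - cp2)
  cc3 <- cc + 0.5 * dt * k2c; cp3 <- cp + 0.5 * dt * k2p
  e3 <- vm * cc3 / (km + cc3)
  k3c <- (u - e3) / vc - a * (cc3 - cp3); k3p <- b * (cc3 - cp3)
  cc4 <- cc + dt * k3c; cp4 <- cp + dt * k3p
  e4 <- vm * cc4 / (km + cc4)
  k4c <- (u - e4) / vc - a * (cc4 - cp4); k4p <- b * (cc4 - cp4)
  c(max(0, cc + dt * (k1c + 2 * k2c + 2 * k3c + k4c) / 6),
    max(0, cp + dt * (k1p + 2 * k2p + 2 * k3p + k4p) / 6),
    el + dt * (e1 + 2 * e2 + 2 * e3 + e4) / 6)
}

#' Advance the pharmacokinetic model one step
#'
#' Integrates the two-compartment Michaelis-Menten system over `dt` minutes
#' with classical fixed-step Runge-Kutta (RK4) under a constant infusion
#' rate. The ODE system is
#' \deqn{dC_c/dt = u/(v_d(1-f)) - k(C_c - C_p)/(1-f) -
#'   v_{max} C_c / ((k_m + C_c) v_d (1-f))}
#' \deqn{dC_p/dt = k (C_c - C_p)/f}
#' with `u` the ethanol mass input in g/min. Cumulative infused and
#' eliminated mass tallies are co-integrated so that mass balance holds to
#' integrator precision.
#'
#' @param state a [pk_state()].
#' @param params a [pk_params()].
#' @param rate_ml_h pump rate held constant over the step, ml/h.
#' @param dt step length, minutes (positive).
#' @return The updated [pk_state()].
#' @export
step_pk <- function(state, params, rate_ml_h, dt) {
  stopifnot(inherits(state, "pk_state"), inherits(params, "pk_params"))
  if (dt <= 0) .stopf("dt must be positive")
  u <- ethanol_mass_rate(rate_ml_h)
  y <- .pk_rk4(state$c_central, state$c_peripheral,
               state$cumulative_eliminated, params, u, dt)
  pk_state(t = state$t + dt, c_central = y[1], c_peripheral = y[2],
           cumulative_infused = state$cumulative_infused + u * dt,
           cumulative_eliminated = y[3])
}

#' Simulate the pharmacokinetic model under a piecewise-constant schedule
#'
#' @param params a [pk_params()].
#' @param schedule data frame with columns `t_min` (start time of each
#'   segment, increasing, first at the simulation start) and `rate_ml_h`;
#'   each rate holds until the next segment.
#' @param t_end end of the simulation, minutes.
#' @param dt integrator step, minutes.
#' @param init a [pk_state()] giving the initial condition.
#' @return A data frame with columns `t_min`, `brac_mg_dl`, `infusion_ml_h`,
#'   plus attributes `final_state` (the end-of-run [pk_state()]).
#' @export
simulate_pk <- function(params, schedule, t_end, dt = 0.05,
                        init = pk_state(t = schedule$t_min[1])) {
  stopifnot(is.data.frame(schedule),
            all(c("t_min", "rate_ml_h") %in% names(schedule)),
            nrow(schedule) >= 1, !is.unsorted(schedule$t_min))
  t0 <- schedule$t_min[1]
  n <- ceiling((t_end - t0) / dt - 1e-9)
  tt <- t0 + dt * (0:n)
  seg <- findInterval(tt, schedule$t_min)
  rates <- schedule$rate_ml_h[pmax(seg, 1)]
  cc <- init$c_central; cp <- init$c_peripheral
  el <- init$cumulative_eliminated; inf <- init$cumulative_infused
  out_brac <- numeric(n + 1)
  out_brac[1] <- cc * 100
  for (i in seq_len(n)) {
    u <- ethanol_mass_rate(rates[i])
    y <- .pk_rk4(cc, cp, el, params, u, dt)
    cc <- y[1]; cp <- y[2]; el <- y[3]
    inf <- inf + u * dt
    out_brac[i + 1] <- cc * 100
  }
  res <- data.frame(t_min = tt, brac_mg_dl = out_brac, infusion_ml_h = rates)
  attr(res, "final_state") <- pk_state(
    t = tt[n + 1], c_central = cc, c_peripheral = cp,
    cumulative_infused = inf, cumulative_eliminated = el)
  res
}

#' Take a (possibly noisy) BrAC reading
#'
#' Models the bedside breathalyzer: the true model BrAC plus zero-mean
#' Gaussian noise, truncated at zero. Uses the current RNG stream; seed with
#' [set.seed()] for reproducibility.
#'
#' @param state a [pk_state()].
#' @param noise_sd measurement noise standard deviation, mg/dL.
#' @return A list of class `brac_reading` with fields `t`, `brac`, `noise_sd`.
#' @export
measure_brac <- function(state, noise_sd = 0) {
  if (noise_sd < 0) .stopf("noise_sd must be nonnegative")
  val <- brac(state)
  if (noise_sd > 0) val <- val + rnorm(1, 0, noise_sd)
  structure(list(t = state$t, brac = max(0, val), noise_sd = noise_sd),
            class = "brac_reading")
}
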