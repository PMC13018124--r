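## Structural model kinetics: closed-form tri-exponential solution of the
## two-compartment first-order-absorption model, multi-dose superposition,
## effect-compartment link and Imax pain model.

## Disposition exponents (alpha, beta) and per-exponential coefficients of the
## unit-bolus-absorption solution. Central concentration after one oral dose D
## at lagged time u = t - t_dose - tlag (u > 0):
##   C(u) = (D ka / V1) * sum_j co_j exp(-lam_j u),  lam = (alpha, beta, ka)
## If ka collides with a disposition exponent the coefficients are singular;
## ka is then nudged by a relative epsilon of 1e-7 (documented fallback;
## plasma_profile(method = "ode") avoids the closed form entirely).
.disposition <- function(params) {
  k10 <- params$cl / params$v1
  k12 <- params$q / params$v1
  k21 <- params$q / params$v2
  s <- k10 + k12 + k21
  root <- sqrt(s * s - 4 * k10 * k21)
  alpha <- (s + root) / 2
  beta <- (s - root) / 2
  ka <- params$ka
  if (min(abs(ka - alpha), abs(ka - beta)) < 1e-8 * ka)
    ka <- ka * (1 + 1e-7)
  lam <- c(alpha, beta, ka)
  co <- c((k21 - alpha) / ((ka - alpha) * (beta - alpha)),
          (k21 - beta) / ((ka - beta) * (alpha - beta)),
          (k21 - ka) / ((alpha - ka) * (beta - ka)))
  list(lam = lam, co = co, ka = ka)
}

## Superposition over the regimen's equally spaced doses (mg/L). The general
## event-schedule workhorses .conc_events / .ce_events live in estimation.R.
.conc_closed <- function(params, regimen, times) {
  td <- dose_times(regimen)
  .conc_events(params, td, rep(regimen$dose, length(td)), times)
}

## Effect-site concentration (ng/mL) by closed form: each plasma exponential
## convolved with the effect-compartment impulse response. Unit conversion
## mg/L -> ng/mL (x1000) happens here, at the PK->PD link, because IC50 is
## reported in ng/mL. Ce carries the steady-state gain ke1/ke2 (no
## normalization): the genotype effect acts through this gain.
.ce_closed <- function(params, regimen, times) {
  td <- dose_times(regimen)
  .ce_events(params, td, rep(regimen$dose, length(td)), times)
}

#' Plasma concentration-time profile
#'
#' Central-compartment concentration (amount / V1, mg/L which is numerically
#' ug/mL) under multi-dose superposition of the closed-form tri-exponential
#' solution of the two-compartment model with first-order absorption and lag
#' time. `method = "ode"` integrates the equivalent three-state ODE system
#' with an adaptive solver (lsoda, rtol 1e-8) instead; the two routes agree to
#' high precision and the ODE route also serves as fallback when the
#' absorption rate collides with a disposition exponent.
#'
#' @param params an `individual_parameters` object
#' @param regimen a [regimen()]
#' @param times nonnegative, strictly increasing evaluation grid (h)
#' @param method `"closed"` (default) or `"ode"`
#' @return a [time_profile()] in mg/L (= ug/mL); zero before
#'   `first_dose_time + tlag`
#' @examples
#' m <- population_model()
#' p <- typical_parameters(m, list(egfr = 84.85, oct2 = "GG"))
#' pr <- plasma_profile(p, regimen(300, tau = 8), seq(0, 8, 0.1))
#' max(pr$values)
#' @export
plasma_profile <- function(params, regimen, times,
                           method = c("closed", "ode")) {
  method <- match.arg(method)
  stopifnot(inherits(params, "individual_parameters"),
            inherits(regimen, "regimen"))
  if (any(times < 0)) stop("plasma_profile: negative times are not allowed")
  if (any(diff(times) <= 0)) stop("plasma_profile: times must be strictly increasing")
  vals <- if (method == "closed") {
    .conc_closed(params, regimen, times)
  } else {
    .conc_ode(params, regimen, times)
  }
  time_profile(times, pmax(vals, 0))
}

## ODE route: states (depot, central amount, peripheral amount); dosing as
## impulse events into the depot at t_dose + tlag.
.conc_ode <- function(params, regimen, times) {
  if (regimen$dose == 0) return(numeric(length(times)))
  ev_times <- dose_times(regimen) + params$tlag
  deriv <- function(t, y, p) {
    list(c(-p$ka * y[1],
           p$ka * y[1] - (p$cl / p$v1 + p$q / p$v1) * y[2] + (p$q / p$v2) * y[3],
           (p$q / p$v1) * y[2] - (p$q / p$v2) * y[3]))
  }
  events <- data.frame(var = "depot", time = ev_times,
                       value = regimen$dose, method = "add")
  grid <- sort(unique(c(0, times, ev_times)))
  sol <- deSolve::lsoda(
    y = c(depot = 0, central = 0, peripheral = 0),
    times = grid, func = deriv, parms = params,
    events = list(data = events), rtol = 1e-8, atol = 1e-10
  )
  cen <- sol[match(times, sol[, "time"]), "central"]
  cen / params$v1
}

#' Effect-site concentration profile
#'
#' Solves `dCe/dt = ke1 * Cp - ke2 * Ce`, `Ce(0) = 0`, for a tabulated plasma
#' profile. The plasma input (mg/L) is converted to ng/mL (x1000) before the
#' link, matching the ng/mL scale of IC50. Between grid points Cp is treated
#' as piecewise linear and the linear ODE is advanced by its exact one-step
#' update, so accuracy is limited only by the grid resolution of the plasma
#' profile (use ~0.1 h steps; the shortest model time constant is 1/ke2).
#'
#' Ce carries the steady-state gain ke1/ke2: for constant plasma Cp the
#' asymptote is `(ke1/ke2) * Cp * 1000` ng/mL. The OCT2 genotype effect acts
#' through this gain.
#'
#' @param params an `individual_parameters` object (uses ke1, ke2)
#' @param plasma a [time_profile()] of plasma concentration in mg/L
#' @return a [time_profile()] of effect-site concentration in ng/mL
#' @export
effect_site_profile <- function(params, plasma) {
  stopifnot(inherits(params, "individual_parameters"),
            inherits(plasma, "time_profile"))
  cp <- 1000 * plasma$values
  t <- plasma$times
  n <- length(t)
  ke1 <- params$ke1
  ke2 <- params$ke2
  ce <- numeric(n)
  if (n > 1 && ke1 > 0) {
    for (i in seq_len(n - 1)) {
      h <- t[i + 1] - t[i]
      E <- exp(-ke2 * h)
      m <- (cp[i + 1] - cp[i]) / h
      ## exact step for dCe/dt = ke1*(c0 + m s) - ke2*Ce on s in [0, h]
      ce[i + 1] <- ce[i] * E +
        ke1 * (cp[i] * (1 - E) / ke2 + m * (h / ke2 - (1 - E) / ke2^2))
    }
  }
  time_profile(t, pmax(ce, 0))
}

#' Pain score and attenuation profiles
#'
#' Inhibitory Imax model on the effect-site concentration:
#' `E(t) = E0 * (1 - Imax * Ce / (IC50 + Ce))`, with pain attenuation
#' expressed as percent reduction from baseline,
#' `100 * (E0 - E(t)) / E0 = 100 * Imax * Ce / (IC50 + Ce)`. With Imax = 1
#' (full inhibition, the final model) the attenuation is independent of E0.
#'
#' @param params an `individual_parameters` object (uses e0, ic50, imax)
#' @param ce a [time_profile()] of effect-site concentration in ng/mL
#' @return list with `score` (VAS time_profile) and `attenuation`
#'   (percent time_profile)
#' @export
pain_profile <- function(params, ce) {
  stopifnot(inherits(params, "individual_parameters"),
            inherits(ce, "time_profile"))
  inhib <- params$imax * ce$values / (params$ic50 + ce$values)
  list(score = time_profile(ce$times, params$e0 * (1 - inhib)),
       attenuation = time_profile(ce$times, 100 * inhib))
}
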