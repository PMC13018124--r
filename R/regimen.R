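#' Dosing regimen
#'
#' Equally spaced oral doses: `n_doses` administrations of `dose` mg every
#' `tau` hours, the first at `first_dose_time`.
#'
#' @param dose amount per administration (mg), >= 0
#' @param tau inter-dose interval (h), > 0
#' @param n_doses number of administrations, >= 1
#' @param first_dose_time time of the first dose (h)
#' @return a `regimen` object
#' @examples
#' regimen(300, tau = 8, n_doses = 105)   # 300 mg TID for 5 weeks
#' @export
regimen <- function(dose, tau, n_doses = 1L, first_dose_time = 0) {
  stopifnot(is.numeric(dose), length(dose) == 1L, dose >= 0,
            is.numeric(tau), length(tau) == 1L, tau > 0,
            n_doses >= 1, first_dose_time >= 0)
  r <- list(dose = dose, tau = tau, n_doses = as.integer(n_doses),
            first_dose_time = first_dose_time)
  class(r) <- "regimen"
  r
}

#' @rdname regimen
#' @param x a `regimen`
#' @return `dose_times()`: numeric vector of administration times (h)
#' @export
dose_times <- function(x) {
  stopifnot(inherits(x, "regimen"))
  x$first_dose_time + x$tau * (seq_len(x$n_doses) - 1)
}

#' @rdname regimen
#' @return `regimen_horizon()`: end of the final dosing interval (h)
#' @export
regimen_horizon <- function(x) {
  stopifnot(inherits(x, "regimen"))
  x$first_dose_time + x$tau * x$n_doses
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("Regimen: %g mg every %g h x %d doses, first at t = %g h\n",
              x$dose, x$tau, x$n_doses, x$first_dose_time))
  invisible(x)
}

#' Time profile container
#'
#' A paired time grid and value vector (plasma mg/L, effect-site ng/mL, pain
#' VAS or attenuation percent depending on context). Times must be strictly
#' increasing.
#'
#' @param times ascending numeric grid (h)
#' @param values numeric vector, same length as `times`
#' @return a `time_profile` object
#' @export
time_profile <- function(times, values) {
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values))
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("time_profile: times must be strictly increasing")
  structure(list(times = times, values = values), class = "time_profile")
}

#' @export
print.time_profile <- function(x, ...) {
  cat(sprintf("time_profile: %d points on [%g, %g] h, values in [%.4g, %.4g]\n",
              length(x$times), min(x$times), max(x$times),
              min(x$values), max(x$values)))
  invisible(x)
}
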