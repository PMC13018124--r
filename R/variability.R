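## Stochastic layer: inter-individual random effects, residual error models
## and left-censoring at the lower limit of quantification.

#' Residual error specification
#'
#' PK observations carry a constant (additive) error, `y = f + a_pk * eps`.
#' PD observations carry a combined error; by default the Monolix "combined1"
#' convention `y = f + (a + b f) * eps`, with a documented switch to the
#' alternative `y = f + sqrt(a^2 + b^2 f^2) * eps` ("combined2").
#'
#' @param pk_add additive PK residual SD (mg/L)
#' @param pd_add additive PD residual SD (VAS units)
#' @param pd_prop proportional PD residual coefficient
#' @param pd_form `"combined1"` (SD = a + b f, default) or `"combined2"`
#'   (SD = sqrt(a^2 + b^2 f^2))
#' @return a `residual_spec` object
#' @export
residual_spec <- function(pk_add = 0.19, pd_add = 0.52, pd_prop = 0.30,
                          pd_form = c("combined1", "combined2")) {
  pd_form <- match.arg(pd_form)
  stopifnot(pk_add >= 0, pd_add >= 0, pd_prop >= 0)
  structure(list(pk_add = pk_add, pd_add = pd_add, pd_prop = pd_prop,
                 pd_form = pd_form),
            class = "residual_spec")
}

#' Residual SD at a given prediction
#'
#' @param spec a [residual_spec()]
#' @param pred model prediction(s)
#' @param channel `"PK"` or `"PD"`
#' @return numeric vector of residual standard deviations
#' @export
residual_sd <- function(spec, pred, channel = c("PK", "PD")) {
  channel <- match.arg(channel)
  stopifnot(inherits(spec, "residual_spec"))
  if (channel == "PK") {
    rep(spec$pk_add, length(pred))
  } else if (spec$pd_form == "combined1") {
    spec$pd_add + spec$pd_prop * pred
  } else {
    sqrt(spec$pd_add^2 + spec$pd_prop^2 * pred^2)
  }
}

#' Sample inter-individual random effects
#'
#' Each parameter's eta is drawn independently from Normal(0, omega^2)
#' (diagonal IIV; the model reports no random-effect correlations).
#' Parameters with omega = 0 get eta = 0 exactly. `method = "lhs"` draws a
#' Latin-hypercube sample instead -- one draw per equiprobable stratum of
#' each marginal, independently permuted across parameters -- which keeps
#' the marginals and independence structure while removing the
#' between-cohort jitter of plain Monte-Carlo sampling; virtual-trial
#' cohorts use it so that cohort summaries estimate the population
#' quantities with minimal simulation noise.
#'
#' @param omega named numeric vector of IIV SDs (names from
#'   [iiv_parameters()])
#' @param n number of subjects
#' @param seed integer seed; same seed, same matrix
#' @param method `"random"` (iid draws, default) or `"lhs"` (stratified)
#' @return n x length(omega) matrix with one column per parameter
#' @export
sample_random_effects <- function(omega, n, seed, method = c("random", "lhs")) {
  method <- match.arg(method)
  stopifnot(n >= 1, all(omega >= 0))
  if (is.null(names(omega)) || !all(names(omega) %in% iiv_parameters()))
    stop("sample_random_effects: omega must be named with IIV parameters")
  set.seed(as.integer(seed))
  draw <- if (method == "random") {
    function(w) stats::rnorm(n, 0, w)
  } else {
    function(w) w * stats::qnorm((sample(n) - stats::runif(n)) / n)
  }
  eta <- vapply(omega, function(w) if (w > 0) draw(w) else numeric(n),
                numeric(n))
  if (n == 1L) eta <- matrix(eta, nrow = 1, dimnames = list(NULL, names(omega)))
  eta
}

#' Apply the residual error model to a predicted profile
#'
#' Adds observation noise according to the channel's error model. PD
#' observations (VAS) are clamped to the bounded 0-10 scale after noise; PK
#' observations may go negative (additive error) and are left for
#' [censor_blq()] to handle.
#'
#' @param profile a [time_profile()] or numeric vector of predictions
#' @param spec a [residual_spec()]
#' @param channel `"PK"` or `"PD"`
#' @param seed integer seed
#' @return numeric vector of observed values
#' @export
apply_residual_error <- function(profile, spec, channel = c("PK", "PD"), seed) {
  channel <- match.arg(channel)
  pred <- if (inherits(profile, "time_profile")) profile$values else profile
  set.seed(as.integer(seed))
  eps <- stats::rnorm(length(pred))
  y <- pred + residual_sd(spec, pred, channel) * eps
  if (channel == "PD") y <- pmin(pmax(y, 0), 10)
  y
}

#' Left-censor observations below the quantification limit
#'
#' Observed values below the LLOQ (including negatives produced by additive
#' noise) are flagged as left-censored on the finite interval [0, LLOQ): the
#' reported value is replaced by the LLOQ and the true value is known only to
#' lie in the interval. Values at or above the LLOQ pass through unchanged.
#' Record count is preserved; the censoring flag partitions the records.
#'
#' @param values numeric vector of observed concentrations (mg/L)
#' @param lloq lower limit of quantification (mg/L), default 0.2
#' @return data.frame with columns `value` (reported), `cens` (0/1),
#'   `lower`, `upper` (censoring interval bounds, NA when uncensored)
#' @examples
#' censor_blq(c(0.1, 0.25), lloq = 0.2)
#' @export
censor_blq <- function(values, lloq = 0.2) {
  stopifnot(is.numeric(values), lloq > 0)
  cens <- as.integer(values < lloq)
  data.frame(
    value = ifelse(cens == 1L, lloq, values),
    cens = cens,
    lower = ifelse(cens == 1L, 0, NA_real_),
    upper = ifelse(cens == 1L, lloq, NA_real_)
  )
}

## Derive a reproducible component seed from a run seed. Keeps results below
## .Machine$integer.max so downstream set.seed() calls stay valid.
derive_seed <- function(seed, component) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}
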