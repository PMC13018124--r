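## Nonlinear mixed-effects estimation of the joint PK/PD model from
## long-format observation datasets. The marginal likelihood (random effects
## integrated out) is evaluated by TMB's Laplace approximation with exact AD
## derivatives; left-censored plasma records contribute the Gaussian
## probability mass on the finite interval [0, LLOQ).

## Closed-form concentration for an arbitrary dose-event schedule (mg/L).
.conc_events <- function(params, dtimes, damts, times) {
  d <- .disposition(params)
  out <- numeric(length(times))
  for (k in seq_along(dtimes)) {
    if (damts[k] == 0) next
    u <- times - dtimes[k] - params$tlag
    pos <- which(u > 0)
    if (!length(pos)) next
    up <- u[pos]
    f <- damts[k] * d$ka / params$v1
    out[pos] <- out[pos] + f * (d$co[1] * exp(-d$lam[1] * up) +
                                d$co[2] * exp(-d$lam[2] * up) +
                                d$co[3] * exp(-d$lam[3] * up))
  }
  out
}

## Closed-form effect-site concentration for a dose-event schedule (ng/mL).
.ce_events <- function(params, dtimes, damts, times) {
  d <- .disposition(params)
  ke2 <- params$ke2
  out <- numeric(length(times))
  if (params$ke1 == 0) return(out)
  for (k in seq_along(dtimes)) {
    if (damts[k] == 0) next
    u <- times - dtimes[k] - params$tlag
    pos <- which(u > 0)
    if (!length(pos)) next
    up <- u[pos]
    f <- 1000 * params$ke1 * damts[k] * d$ka / params$v1
    acc <- 0
    for (j in 1:3) {
      dlt <- ke2 - d$lam[j]
      term <- if (abs(dlt) > 1e-9) (exp(-d$lam[j] * up) - exp(-ke2 * up)) / dlt
              else up * exp(-ke2 * up)
      acc <- acc + d$co[j] * term
    }
    out[pos] <- out[pos] + f * acc
  }
  out
}

## Model predictions for one subject's dataset rows (doses + observations).
.predict_rows <- function(params, rows) {
  obs <- rows[rows$EVID == 0L, , drop = FALSE]
  dtimes <- rows$TIME[rows$EVID == 1L]
  damts <- rows$AMT[rows$EVID == 1L]
  pred <- numeric(nrow(obs))
  pk <- obs$DVID == 1L
  if (any(pk)) pred[pk] <- .conc_events(params, dtimes, damts, obs$TIME[pk])
  if (any(!pk)) {
    ce <- .ce_events(params, dtimes, damts, obs$TIME[!pk])
    pred[!pk] <- params$e0 * (1 - params$imax * ce / (params$ic50 + ce))
  }
  cbind(obs, data.frame(PRED = pred))
}

#' Conditional log-likelihood contribution of one subject
#'
#' Given realized individual parameters, sums the observation-level
#' log-likelihood over one subject's records: uncensored records contribute
#' the Gaussian log-density under the channel's residual model; left-censored
#' plasma records contribute the log probability mass of the Gaussian on the
#' finite censoring interval [0, LLOQ). This is the conditional (given eta)
#' contribution that the marginal likelihood integrates.
#'
#' @param ind_params an `individual_parameters` object
#' @param rows dataset rows for one subject (dose and observation records)
#' @param residual a [residual_spec()]
#' @return scalar log-likelihood contribution
#' @export
observation_log_likelihood <- function(ind_params, rows, residual) {
  stopifnot(inherits(ind_params, "individual_parameters"),
            inherits(residual, "residual_spec"))
  pr <- .predict_rows(ind_params, rows)
  ll <- 0
  for (k in seq_len(nrow(pr))) {
    channel <- if (pr$DVID[k] == 1L) "PK" else "PD"
    sd <- residual_sd(residual, pr$PRED[k], channel)
    if (sd <= 0 && pr$CENS[k] == 1L)
      stop("observation_log_likelihood: censored record with nonpositive residual SD")
    if (pr$CENS[k] == 1L) {
      mass <- stats::pnorm(pr$LLOQ[k], pr$PRED[k], sd) -
        stats::pnorm(0, pr$PRED[k], sd)
      ll <- ll + log(max(mass, 1e-12))   # same floor as the Laplace kernel
    } else if (channel == "PD" && !is.na(pr$DV[k]) && pr$DV[k] >= 10 - 1e-9) {
      ## boundary value on the bounded VAS scale: mass at or above 10
      ll <- ll + log(max(stats::pnorm(10, pr$PRED[k], sd, lower.tail = FALSE), 1e-12))
    } else if (channel == "PD" && !is.na(pr$DV[k]) && pr$DV[k] <= 1e-9) {
      ll <- ll + log(max(stats::pnorm(0, pr$PRED[k], sd), 1e-12))
    } else {
      ll <- ll + stats::dnorm(pr$DV[k], pr$PRED[k], sd, log = TRUE)
    }
  }
  ll
}

## ---- TMB plumbing ---------------------------------------------------------

.iiv_order <- c("tlag", "ka", "cl", "v1", "q", "ke1", "e0")

## Assemble the TMB data list from a validated dataset. Missing eGFR is
## imputed by the dataset median (the covariate-model convention).
.tmb_data <- function(dataset) {
  validate_dataset(dataset)
  ids <- sort(unique(dataset$ID))
  idx <- match(dataset$ID, ids)
  sub1 <- !duplicated(dataset$ID)
  egfr <- dataset$EGFR[sub1][order(idx[sub1])]
  med <- stats::median(egfr, na.rm = TRUE)
  if (!is.finite(med)) stop("no eGFR values available for imputation")
  egfr[is.na(egfr)] <- med
  g_oct2 <- genotype_code(dataset$OCT2[sub1][order(idx[sub1])], "oct2")
  x_null <- genotype_code(dataset$OCTN1[sub1][order(idx[sub1])], "octn1")

  obs <- dataset[dataset$EVID == 0L, ]
  obs <- obs[order(match(obs$ID, ids), obs$TIME), ]
  ## VAS boundary values: the bounded 0-10 scale pins scores at its limits,
  ## so recorded 10s (0s) enter the likelihood as the probability mass at or
  ## above 10 (at or below 0) -- internal codes 2 and 3
  pd_hi <- obs$DVID == 2L & !is.na(obs$DV) & obs$DV >= 10 - 1e-9
  pd_lo <- obs$DVID == 2L & !is.na(obs$DV) & obs$DV <= 1e-9
  obs$CENS[pd_hi] <- 2L
  obs$CENS[pd_lo] <- 3L
  dos <- dataset[dataset$EVID == 1L, ]
  dos <- dos[order(match(dos$ID, ids), dos$TIME), ]

  ## collapse each subject's dosing history into trains of equally spaced
  ## equal doses (t0, tau, n, amt); irregular schedules fall back to
  ## single-dose trains
  train_t0 <- train_tau <- train_amt <- numeric(0)
  train_n <- train_sub <- integer(0)
  for (i in seq_along(ids)) {
    dd <- dos[dos$ID == ids[i], ]
    j <- 1L
    while (j <= nrow(dd)) {
      t0 <- dd$TIME[j]; amt <- dd$AMT[j]; n_tr <- 1L; tau <- 1
      if (j < nrow(dd)) {
        tau0 <- dd$TIME[j + 1] - dd$TIME[j]
        while (j + n_tr <= nrow(dd) &&
               abs(dd$AMT[j + n_tr] - amt) < 1e-9 &&
               abs(dd$TIME[j + n_tr] - (t0 + n_tr * tau0)) < 1e-9)
          n_tr <- n_tr + 1L
        if (n_tr > 1L) tau <- tau0
      }
      train_t0 <- c(train_t0, t0); train_tau <- c(train_tau, tau)
      train_amt <- c(train_amt, amt)
      train_n <- c(train_n, n_tr); train_sub <- c(train_sub, i)
      j <- j + n_tr
    }
  }

  ## observation-train pairs with the number of train doses at or before
  ## each observation (data-only quantities, so the AD tape never branches
  ## on parameters)
  obs_sub <- match(obs$ID, ids)
  pair_obs <- pair_train <- pair_m <- integer(0)
  for (tr in seq_along(train_t0)) {
    k <- which(obs_sub == train_sub[tr])
    if (!length(k)) next
    m <- floor((obs$TIME[k] - train_t0[tr]) / train_tau[tr] + 1e-9) + 1
    m <- pmin(pmax(m, 0), train_n[tr])
    pair_obs <- c(pair_obs, k - 1L)
    pair_train <- c(pair_train, rep(tr - 1L, length(k)))
    pair_m <- c(pair_m, as.integer(m))
  }

  list(
    obs_time = obs$TIME, obs_sub = as.integer(obs_sub - 1L),
    obs_dvid = as.integer(obs$DVID),
    obs_dv = ifelse(is.na(obs$DV), 0, obs$DV),
    obs_cens = as.integer(obs$CENS), obs_lloq = obs$LLOQ,
    train_t0 = train_t0, train_tau = train_tau, train_amt = train_amt,
    pair_obs = pair_obs, pair_train = pair_train, pair_m = pair_m,
    egfr = as.numeric(egfr), g_oct2 = as.numeric(g_oct2),
    x_null = as.numeric(x_null), egfr_ref = 84.85,
    n_subj = length(ids), ids = ids
  )
}

## Heuristic initial values on the estimation scale: CL from the naive
## steady-state mass balance (dose rate over mean concentration) of
## multiple-dose subjects when available, E0 from early pain scores;
## everything else from documented generic defaults.
.default_inits <- function(dataset) {
  cl0 <- 8
  dos <- dataset[dataset$EVID == 1L, ]
  multi <- names(which(table(dos$ID) >= 4))
  if (length(multi)) {
    cls <- vapply(multi, function(id) {
      dd <- dos[dos$ID == id, ]
      rate <- mean(dd$AMT) / stats::median(diff(sort(dd$TIME)))
      cc <- dataset[dataset$ID == id & dataset$EVID == 0L &
                      dataset$DVID == 1L & dataset$CENS == 0L, "DV"]
      if (length(cc) && mean(cc) > 0) rate / mean(cc) else NA_real_
    }, 0)
    if (any(is.finite(cls))) cl0 <- stats::median(cls, na.rm = TRUE)
  }
  e00 <- 7
  pd <- dataset[dataset$EVID == 0L & dataset$DVID == 2L, ]
  if (nrow(pd)) {
    first <- pd[!duplicated(pd$ID), "DV"]
    if (length(first)) e00 <- min(max(stats::median(first, na.rm = TRUE), 1), 9)
  }
  list(log_tlag = log(0.3), log_ka = log(0.2), log_cl = log(cl0),
       log_v1 = log(20), log_q = log(5), log_v2 = log(200),
       log_ke1 = log(0.3), lgt_e0 = stats::qlogis(e00 / 10),
       beta_egfr = 0, beta_oct2 = 0, beta_null = 0,
       log_ic50 = log(263.11), log_ke2 = log(1),
       log_om = log(c(0.5, 0.3, 0.5, 0.5, 0.5, 1.5, 0.8)),
       log_sig_pk = log(0.3), log_sig_pd_a = log(0.5), log_sig_pd_b = log(0.2))
}

.map_fixed <- function() factor(NA)

#' Fit the population PK/PD model by Laplace-approximation ML
#'
#' Maximizes the marginal likelihood of the mixed-effects model (random
#' effects integrated out by the Laplace approximation with exact AD
#' derivatives) under the censored observation likelihood. Follows the
#' staged development sequence: `stage = "pk"` fits the PK sub-model to
#' plasma data alone; `stage = "pd"` fixes the population PK parameters (from
#' `inits`, typically a prior PK fit) and estimates the PD side; `stage =
#' "joint"` estimates all PK/PD parameters simultaneously. IC50, ke2 and
#' Imax are structurally fixed (the final-model convention) unless listed in
#' `estimate_fixed`.
#'
#' @param dataset validated observation data.frame
#' @param stage `"joint"`, `"pk"` or `"pd"`
#' @param covariates character subset of `c("egfr_cl", "oct2_ke1", "null_cl")`
#'   naming active covariate effects (power model for eGFR on CL,
#'   proportional-exponential for genotype on ke1, and a
#'   proportional-exponential null candidate -- the OCTN1 code -- on CL);
#'   inactive coefficients are fixed at 0
#' @param fixed named list of fixed values for `ic50`, `ke2` and/or the
#'   residual SDs `sigma_pk_add`, `sigma_pd_add`, `sigma_pd_prop` (fixing a
#'   residual SD supports noiseless identifiability checks)
#' @param iiv set `FALSE` to drop all random effects (naive pooled fit of the
#'   structural model)
#' @param estimate_fixed character vector naming members of the fixed trio to
#'   free (e.g. `"ke2"` for the ke1 != ke2 variant exploration)
#' @param inits named list overriding the heuristic initial values (estimation
#'   scale, see [population_model()] fields)
#' @param n_starts number of optimizer starts; starts after the first jitter
#'   the initial values (multi-start guard against local optima)
#' @param seed integer seed for the jitter
#' @param control passed to [stats::nlminb()]
#' @return a `fit_result` list: `estimates` (a [population_model()]), `ofv`
#'   (-2 log-likelihood), `convergence` (logical), `eta` (empirical-Bayes
#'   modes, n_subj x 7), `par` (estimation-scale parameters), `opt`, `stage`,
#'   `covariates`, `n_subj`, `n_obs`
#' @export
fit_population_model <- function(dataset,
                                 stage = c("joint", "pk", "pd"),
                                 covariates = c("egfr_cl", "oct2_ke1"),
                                 fixed = list(ic50 = 263.11, ke2 = 1),
                                 estimate_fixed = character(0),
                                 inits = NULL, iiv = TRUE, n_starts = 1, seed = 1,
                                 control = list(iter.max = 600, eval.max = 1200)) {
  stage <- match.arg(stage)
  stopifnot(all(covariates %in% c("egfr_cl", "oct2_ke1", "null_cl")))
  if (stage == "pk")
    dataset <- dataset[dataset$EVID == 1L | dataset$DVID %in% 1L, ]
  if (!any(dataset$EVID == 0L)) stop("fit_population_model: dataset has no observations")
  dat <- .tmb_data(dataset)
  has_pd <- any(dat$obs_dvid == 2L)
  eta_active <- rep(1L, 7)
  if (!has_pd) eta_active[6:7] <- 0L
  if (!iiv) eta_active[] <- 0L

  init <- .default_inits(dataset)
  if (!is.null(inits)) init[names(inits)] <- inits
  if (!is.null(fixed$ic50)) init$log_ic50 <- log(fixed$ic50)
  if (!is.null(fixed$ke2)) init$log_ke2 <- log(fixed$ke2)

  map <- list()
  if (!"ic50" %in% estimate_fixed) map$log_ic50 <- .map_fixed()
  if (!"ke2" %in% estimate_fixed) map$log_ke2 <- .map_fixed()
  sig_par <- c(sigma_pk_add = "log_sig_pk", sigma_pd_add = "log_sig_pd_a",
               sigma_pd_prop = "log_sig_pd_b")
  for (nm in intersect(names(sig_par), names(fixed))) {
    init[[sig_par[[nm]]]] <- log(fixed[[nm]])
    map[[sig_par[[nm]]]] <- .map_fixed()
  }
  if (!"egfr_cl" %in% covariates) map$beta_egfr <- .map_fixed()
  if (!"oct2_ke1" %in% covariates || !has_pd) map$beta_oct2 <- .map_fixed()
  if (!"null_cl" %in% covariates) map$beta_null <- .map_fixed()
  om_map <- seq_len(7)
  if (!has_pd) {
    for (nm in c("log_ke1", "lgt_e0", "log_sig_pd_a", "log_sig_pd_b"))
      map[[nm]] <- .map_fixed()
    om_map[6:7] <- NA
  }
  if (stage == "pd") {
    for (nm in c("log_tlag", "log_ka", "log_cl", "log_v1", "log_q", "log_v2",
                 "beta_egfr", "beta_null", "log_sig_pk"))
      map[[nm]] <- .map_fixed()
    om_map[1:5] <- NA
  }
  if (!iiv) om_map[] <- NA
  map$log_om <- factor(om_map)
  eta_map <- matrix(seq_len(dat$n_subj * 7), dat$n_subj, 7)
  eta_map[, which(eta_active == 0L)] <- NA
  map$eta <- factor(eta_map)

  pars <- init
  pars$eta <- matrix(0, dat$n_subj, 7)
  tmb_dat <- dat[setdiff(names(dat), c("ids", "n_subj"))]
  tmb_dat$eta_active <- eta_active

  set.seed(as.integer(seed))
  best <- NULL
  last_error <- NULL
  for (st in seq_len(n_starts)) {
    p0 <- pars
    if (st > 1) {
      for (nm in setdiff(names(init), c("log_ic50", "log_ke2")))
        p0[[nm]] <- init[[nm]] + stats::rnorm(length(init[[nm]]), 0, 0.3)
    }
    obj <- TMB::MakeADFun(data = tmb_dat, parameters = p0, map = map,
                          random = if (any(eta_active == 1L)) "eta" else NULL,
                          DLL = "gabapkpd", silent = TRUE)
    opt <- tryCatch(
      suppressWarnings(stats::nlminb(obj$par, obj$fn, obj$gr, control = control)),
      error = function(e) { last_error <<- conditionMessage(e); NULL }
    )
    if (is.null(opt) || !is.finite(opt$objective)) next
    ## the lag time makes the conditional likelihood only piecewise smooth,
    ## so nlminb often stops with "false convergence" at the optimum; accept
    ## the point if a short restart cannot improve it, otherwise keep going
    polished <- opt$convergence == 0
    rc <- control
    rc$iter.max <- 60
    rc$eval.max <- 120
    for (r in 1:2) {
      if (polished) break
      opt2 <- tryCatch(
        suppressWarnings(stats::nlminb(opt$par, obj$fn, obj$gr, control = rc)),
        error = function(e) NULL
      )
      if (is.null(opt2) || !is.finite(opt2$objective)) break
      if (opt$objective - opt2$objective < 1e-3) polished <- TRUE
      opt <- opt2
    }
    opt$polished <- polished
    if (is.null(best) || opt$objective < best$opt$objective)
      best <- list(obj = obj, opt = opt)
  }
  if (is.null(best)) {
    return(structure(list(estimates = NULL, ofv = NA_real_, convergence = FALSE,
                          eta = NULL, par = NULL, opt = NULL, stage = stage,
                          covariates = covariates, n_subj = dat$n_subj,
                          n_obs = length(dat$obs_time), error = last_error),
                     class = "fit_result"))
  }
  obj <- best$obj; opt <- best$opt
  ## nlminb's "false convergence" code is frequent at genuine optima of
  ## Laplace objectives; judge convergence by the outer gradient norm.
  grad_ok <- tryCatch(max(abs(obj$gr(opt$par))) < 0.1, error = function(e) FALSE)
  pl <- obj$env$parList(opt$par, obj$env$last.par.best)
  est <- population_model(
    tlag_pop = exp(pl$log_tlag), ka_pop = exp(pl$log_ka),
    cl_pop = exp(pl$log_cl), v1_pop = exp(pl$log_v1),
    q_pop = exp(pl$log_q), v2_pop = exp(pl$log_v2),
    ke1_pop = exp(pl$log_ke1), ke2 = exp(pl$log_ke2),
    e0_pop = 10 * stats::plogis(pl$lgt_e0),
    ic50 = exp(pl$log_ic50), imax = 1,
    beta_egfr_cl = pl$beta_egfr, egfr_ref = 84.85,
    beta_oct2_ke1 = pl$beta_oct2,
    omega = stats::setNames(exp(pl$log_om), .iiv_order),
    sigma_pk_add = exp(pl$log_sig_pk),
    sigma_pd_add = exp(pl$log_sig_pd_a),
    sigma_pd_prop = exp(pl$log_sig_pd_b)
  )
  eta <- pl$eta
  colnames(eta) <- .iiv_order
  structure(list(estimates = est, ofv = 2 * opt$objective,
                 convergence = is.finite(opt$objective) &&
                   (opt$convergence == 0 || isTRUE(opt$polished) || grad_ok),
                 eta = eta, par = opt$par, parlist = pl[setdiff(names(pl), "eta")],
                 opt = opt, stage = stage,
                 covariates = covariates, n_subj = dat$n_subj,
                 n_obs = length(dat$obs_time), ids = dat$ids),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("PK/PD fit (%s stage): %d subjects, %d observations\n",
              x$stage, x$n_subj, x$n_obs))
  cat(sprintf("  OFV (-2LL): %.3f | converged: %s | covariates: %s\n",
              x$ofv, x$convergence,
              if (length(x$covariates)) paste(x$covariates, collapse = ", ") else "none"))
  if (!is.null(x$estimates)) print(x$estimates)
  invisible(x)
}

#' Parameter table of a fit
#'
#' Natural-scale estimates in a layout mirroring the reported parameter
#' table: fixed effects, covariate coefficients, IIV SDs, residual SDs.
#'
#' @param fit a `fit_result`
#' @return data.frame with columns `parameter`, `estimate`
#' @export
fit_parameter_table <- function(fit) {
  e <- fit$estimates
  if (is.null(e)) stop("fit did not converge; no estimates available")
  vals <- c(tlag = e$tlag_pop, ka = e$ka_pop, cl = e$cl_pop,
            beta_egfr_cl = e$beta_egfr_cl, v1 = e$v1_pop, q = e$q_pop,
            v2 = e$v2_pop, ke1 = e$ke1_pop, beta_oct2_ke1 = e$beta_oct2_ke1,
            e0 = e$e0_pop, ic50 = e$ic50, ke2 = e$ke2,
            stats::setNames(e$omega, paste0("omega_", names(e$omega))),
            sigma_pk_add = e$sigma_pk_add, sigma_pd_add = e$sigma_pd_add,
            sigma_pd_prop = e$sigma_pd_prop)
  data.frame(parameter = names(vals), estimate = unname(vals))
}

#' Stepwise covariate selection by likelihood-ratio test
#'
#' Forward inclusion / backward elimination on the objective function value
#' (-2 log-likelihood): a candidate enters when it drops the OFV by more
#' than 3.84 per degree of freedom (p < 0.05, chi-square 1 df) and survives
#' backward deletion only if its removal raises the OFV by at least 6.63
#' (p < 0.01). Missing continuous covariates are median-imputed before
#' fitting. Every tested step is recorded in the trace.
#'
#' @param dataset observation data.frame
#' @param candidates covariate effect names as in [fit_population_model()]
#' @param stage model stage to run the selection on (`"pk"` covers the
#'   CL-side candidates at a fraction of the joint-fit cost)
#' @param forward_dofv,backward_dofv LRT thresholds per df
#' @param base_inits optional initial values for the base (no-covariate) fit,
#'   e.g. a previous fit's `parlist`; candidate fits are chained from their
#'   parent model's optimum so that nested OFV comparisons happen within one
#'   likelihood basin
#' @param ... passed to [fit_population_model()]
#' @return list with `selected` (character), `trace` (data.frame of every
#'   tested step) and `fits` (the base and final fit)
#' @export
stepwise_covariate_selection <- function(dataset,
                                         candidates = c("egfr_cl", "null_cl"),
                                         stage = "pk",
                                         forward_dofv = 3.84,
                                         backward_dofv = 6.63,
                                         base_inits = NULL, ...) {
  selected <- character(0)
  trace <- list()
  cache <- new.env(parent = emptyenv())
  warm <- base_inits
  beta0 <- list()   # EBE-regression starting values per candidate
  fit_with <- function(cv) {
    key <- paste0("cv:", paste(sort(cv), collapse = "+"))
    if (!is.null(cache[[key]])) return(cache[[key]])
    w <- warm
    ## a candidate coefficient started at 0 from the parent optimum sits in
    ## a flat region (the subject-level etas have absorbed the covariate
    ## signal); start it at the empirical-Bayes regression slope instead
    for (cand in intersect(cv, names(beta0))) {
      nm <- c(egfr_cl = "beta_egfr", oct2_ke1 = "beta_oct2",
              null_cl = "beta_null")[[cand]]
      if (!is.null(w) && is.null(w[[nm]])) w[[nm]] <- beta0[[cand]]
      else if (!is.null(w)) w[[nm]] <- beta0[[cand]]
    }
    f <- fit_population_model(dataset, stage = stage, covariates = cv,
                              inits = w, ...)
    cache[[key]] <- f
    f
  }
  base <- fit_with(selected)
  ## candidate fits are warm-started from the current selected-set optimum so
  ## nested OFV comparisons stay within one likelihood basin
  if (isTRUE(base$convergence)) {
    warm <- base$parlist
    dat0 <- .tmb_data(if (stage == "pk")
      dataset[dataset$EVID == 1L | dataset$DVID %in% 1L, ] else dataset)
    slope <- function(y, x) {
      if (stats::var(x) == 0) return(0)
      unname(stats::coef(stats::lm(y ~ x))[2])
    }
    beta0$egfr_cl <- slope(base$eta[, "cl"], log(dat0$egfr / dat0$egfr_ref))
    beta0$null_cl <- slope(base$eta[, "cl"], dat0$x_null)
    if (any(dat0$obs_dvid == 2L))
      beta0$oct2_ke1 <- slope(base$eta[, "ke1"], dat0$g_oct2)
  }
  ofv <- base$ofv
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    deltas <- vapply(remaining, function(cand) {
      f <- fit_with(c(selected, cand))
      d <- ofv - f$ofv
      trace[[length(trace) + 1]] <<- data.frame(
        phase = "forward", candidate = cand, ofv = f$ofv, delta_ofv = d,
        decision = if (is.finite(d) && d > forward_dofv) "eligible" else "rejected")
      if (is.finite(d)) d else -Inf
    }, 0)
    if (max(deltas) <= forward_dofv) break
    win <- remaining[which.max(deltas)]
    selected <- c(selected, win)
    win_fit <- cache[[paste0("cv:", paste(sort(selected), collapse = "+"))]]
    if (isTRUE(win_fit$convergence)) warm <- win_fit$parlist
    ofv <- ofv - max(deltas)
    trace[[length(trace) + 1]] <- data.frame(
      phase = "forward", candidate = win, ofv = ofv, delta_ofv = max(deltas),
      decision = "included")
  }
  repeat {
    if (!length(selected)) break
    rises <- vapply(selected, function(cand) {
      f <- fit_with(setdiff(selected, cand))
      r <- f$ofv - ofv
      trace[[length(trace) + 1]] <<- data.frame(
        phase = "backward", candidate = cand, ofv = f$ofv, delta_ofv = r,
        decision = if (is.finite(r) && r < backward_dofv) "removable" else "retained")
      if (is.finite(r)) r else Inf
    }, 0)
    if (min(rises) >= backward_dofv) break
    drop <- selected[which.min(rises)]
    selected <- setdiff(selected, drop)
    ofv <- ofv + min(rises)
    trace[[length(trace) + 1]] <- data.frame(
      phase = "backward", candidate = drop, ofv = ofv, delta_ofv = min(rises),
      decision = "removed")
  }
  final <- fit_with(selected)
  list(selected = selected, trace = do.call(rbind, trace),
       fits = list(base = base, final = final))
}

#' Non-parametric bootstrap confidence intervals
#'
#' Resamples subjects with replacement, refits, and reports per-parameter
#' bootstrap medians with 2.5th/97.5th percentiles. Failed fits are retried
#' with jittered initial values up to `max_retries` times per replicate; the
#' convergence rate (converged / attempted replicates) is reported and a
#' warning raised when it falls below 96%.
#'
#' @param dataset observation data.frame
#' @param reps bootstrap replicates (the reference analysis used 500)
#' @param max_retries retry budget per replicate
#' @param seed integer seed
#' @param ... passed to [fit_population_model()]
#' @return list with `table` (parameter, median, lower, upper),
#'   `convergence_rate`, `reps`
#' @export
bootstrap_ci <- function(dataset, reps = 500, max_retries = 20, seed = 1, ...) {
  stopifnot(reps >= 1)
  ids <- unique(dataset$ID)
  results <- vector("list", reps)
  converged <- logical(reps)
  for (r in seq_len(reps)) {
    set.seed(derive_seed(seed, paste0("boot", r)))
    draw <- sample(ids, length(ids), replace = TRUE)
    pieces <- lapply(seq_along(draw), function(j) {
      sub <- dataset[dataset$ID == draw[j], ]
      sub$ID <- j
      sub
    })
    bdat <- do.call(rbind, pieces)
    fit <- NULL
    for (try in seq_len(max_retries + 1)) {
      fit <- fit_population_model(bdat, seed = derive_seed(seed, paste0("bootfit", r, "_", try)),
                                  n_starts = if (try == 1) 1 else 2, ...)
      if (isTRUE(fit$convergence)) break
    }
    converged[r] <- isTRUE(fit$convergence)
    if (converged[r]) results[[r]] <- fit_parameter_table(fit)
  }
  rate <- mean(converged)
  if (rate < 0.96)
    warning(sprintf("bootstrap convergence rate %.1f%% is below 96%%", 100 * rate))
  ok <- results[converged]
  if (!length(ok)) stop("bootstrap_ci: no bootstrap replicate converged")
  mat <- vapply(ok, function(tb) tb$estimate, numeric(nrow(ok[[1]])))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = nrow(ok[[1]]))
  qs <- t(apply(mat, 1, stats::quantile, probs = c(0.5, 0.025, 0.975), type = 7))
  list(table = data.frame(parameter = ok[[1]]$parameter,
                          median = qs[, 1], lower = qs[, 2], upper = qs[, 3]),
       convergence_rate = rate, reps = reps)
}

#' Visual predictive check bands
#'
#' Simulates `n_rep` replicate datasets under the model with the original
#' design (same subjects, dosing histories, sampling times and covariates;
#' fresh random effects and residual noise; plasma values below the LLOQ
#' reported at the LLOQ, matching the observed-data convention), then
#' compares observed percentiles (10/50/90) per time bin with the envelope
#' (2.5/50/97.5% across replicates) of the same simulated percentiles,
#' stratified by study when a STUDY column is present, and by channel.
#'
#' @param dataset observation data.frame
#' @param model a [population_model()] (typically `fit$estimates`)
#' @param n_rep number of simulation replicates
#' @param seed integer seed
#' @param n_bins maximum number of time bins per stratum
#' @return data.frame: stratum, dvid, bin time, observed p10/p50/p90 and, for
#'   each, the simulated envelope columns `sim_<p>_lo/md/hi`
#' @export
vpc_bands <- function(dataset, model = population_model(), n_rep = 200,
                      seed = 1, n_bins = 8) {
  validate_dataset(dataset)
  strata <- if ("STUDY" %in% names(dataset)) dataset$STUDY else rep("all", nrow(dataset))
  obs_mask <- dataset$EVID == 0L
  rspec <- residual_spec(model$sigma_pk_add, model$sigma_pd_add, model$sigma_pd_prop)
  ids <- unique(dataset$ID)
  dat <- .tmb_data(dataset)
  egfr_by_id <- stats::setNames(dat$egfr, dat$ids)

  simulate_once <- function(rep_seed) {
    eta <- sample_random_effects(model$omega, length(ids), rep_seed)
    out <- rep(NA_real_, nrow(dataset))
    for (j in seq_along(ids)) {
      rows <- dataset[dataset$ID == ids[j], ]
      typ <- typical_parameters(model, list(egfr = egfr_by_id[[as.character(ids[j])]],
                                            oct2 = rows$OCT2[1]))
      p <- individual_parameters(typ, eta[j, ])
      pr <- .predict_rows(p, rows)
      pk <- pr$DVID == 1L
      y <- numeric(nrow(pr))
      if (any(pk))
        y[pk] <- apply_residual_error(pr$PRED[pk], rspec, "PK",
                                      derive_seed(rep_seed, paste0("pk", j)))
      if (any(!pk))
        y[!pk] <- apply_residual_error(pr$PRED[!pk], rspec, "PD",
                                       derive_seed(rep_seed, paste0("pd", j)))
      if (any(pk)) y[pk] <- censor_blq(y[pk], rows$LLOQ[rows$EVID == 0L][pk][1])$value
      out[obs_mask & dataset$ID == ids[j]] <- y
    }
    out
  }

  sims <- vapply(seq_len(n_rep), function(r) simulate_once(derive_seed(seed, paste0("vpc", r))),
                 numeric(nrow(dataset)))
  if (is.null(dim(sims))) sims <- matrix(sims, ncol = n_rep)

  probs <- c(0.1, 0.5, 0.9)
  res <- list()
  for (st in unique(strata)) {
    for (dvid in intersect(c(1L, 2L), dataset$DVID[obs_mask & strata == st])) {
      sel <- which(obs_mask & strata == st & dataset$DVID == dvid)
      tt <- dataset$TIME[sel]
      ut <- sort(unique(tt))
      bin <- if (length(ut) <= n_bins) tt else {
        br <- unique(stats::quantile(tt, seq(0, 1, length.out = n_bins + 1)))
        mids <- (utils::head(br, -1) + utils::tail(br, -1)) / 2
        mids[cut(tt, br, include.lowest = TRUE, labels = FALSE)]
      }
      for (b in sort(unique(bin))) {
        k <- sel[bin == b]
        obs_q <- stats::quantile(dataset$DV[k], probs, na.rm = TRUE, type = 7)
        sim_q <- apply(sims[k, , drop = FALSE], 2, stats::quantile,
                       probs = probs, type = 7)
        env <- apply(sim_q, 1, stats::quantile, probs = c(0.025, 0.5, 0.975), type = 7)
        row <- data.frame(stratum = st, dvid = dvid, time = b, n = length(k),
                          obs_p10 = obs_q[1], obs_p50 = obs_q[2], obs_p90 = obs_q[3])
        for (pi in seq_along(probs)) {
          nm <- paste0("sim_p", probs[pi] * 100)
          row[[paste0(nm, "_lo")]] <- env[1, pi]
          row[[paste0(nm, "_md")]] <- env[2, pi]
          row[[paste0(nm, "_hi")]] <- env[3, pi]
        }
        res[[length(res) + 1]] <- row
      }
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
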