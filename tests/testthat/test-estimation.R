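test_that("observation log-likelihood matches the censored Gaussian formulas", {
  p <- typ_params()
  spec <- residual_spec()
  base_cols <- data.frame(LLOQ = 0.2, EGFR = 90, OCT2 = "GG", OCTN1 = "CC",
                          AGE = 50, WT = 80, SEX = "F")
  dose_row <- cbind(data.frame(ID = 1L, TIME = 0, EVID = 1L, AMT = 300,
                               DVID = NA_integer_, DV = NA_real_, CENS = 0L), base_cols)
  # uncensored record observed exactly at the prediction: Gaussian mode
  t_obs <- 4
  pred <- plasma_profile(p, regimen(300, 24, 1), c(t_obs))$values
  obs_row <- cbind(data.frame(ID = 1L, TIME = t_obs, EVID = 0L, AMT = NA,
                              DVID = 1L, DV = pred, CENS = 0L), base_cols)
  ll <- observation_log_likelihood(p, rbind(dose_row, obs_row), spec)
  expect_equal(ll, -0.5 * log(2 * pi * 0.19^2))
  # censored record with zero prediction: normal mass on [0, LLOQ)
  cens_row <- cbind(data.frame(ID = 1L, TIME = 0.1, EVID = 0L, AMT = NA,
                               DVID = 1L, DV = 0.2, CENS = 1L), base_cols)
  ll_cens <- observation_log_likelihood(p, rbind(dose_row, cens_row), spec)
  expect_equal(ll_cens, log(pnorm(0.2 / 0.19) - 0.5))
  # contributions are additive over records
  both <- observation_log_likelihood(p, rbind(dose_row, obs_row, cens_row), spec)
  expect_equal(both, ll + ll_cens)
})

test_that("noiseless single-subject data identify the structural PK parameters", {
  p <- typ_params(egfr = 84.85)
  reg <- regimen(300, 24, 1)
  tt <- c(0.5, 1, 2, 3, 4, 6, 8, 10, 12, 16, 24, 36, 48)
  pred <- plasma_profile(p, reg, tt)$values
  ds <- data.frame(ID = 1L, TIME = c(0, tt), EVID = c(1L, rep(0L, length(tt))),
                   AMT = c(300, rep(NA, length(tt))),
                   DVID = c(NA, rep(1L, length(tt))),
                   DV = c(NA, pred), CENS = 0L, LLOQ = 0.001,
                   EGFR = 84.85, OCT2 = "GG", OCTN1 = "CC",
                   AGE = 50, WT = 80, SEX = "F")
  fit <- fit_population_model(ds, stage = "pk", covariates = character(0),
                              iiv = FALSE, fixed = list(sigma_pk_add = 0.02),
                              inits = list(log_tlag = log(0.34), log_ka = log(0.14)),
                              seed = 1)
  expect_true(fit$convergence)
  # the Laplace objective reduces to exact least squares here; the TMB
  # kinetics must reproduce the R closed form that generated the data
  expect_equal(fit$estimates$cl_pop, p$cl, tolerance = 0.02)
  expect_equal(fit$estimates$v1_pop, p$v1, tolerance = 0.05)
  expect_equal(fit$estimates$ka_pop, p$ka, tolerance = 0.05)
})

test_that("a constant covariate column leaves the likelihood unchanged", {
  ds <- small_dataset()
  ds$OCTN1 <- "CC"   # covariate with no contrast: beta is unidentified, OFV nested
  f0 <- fit_population_model(ds, stage = "pk", covariates = character(0), seed = 1,
                             control = list(iter.max = 300, eval.max = 600, rel.tol = 1e-5))
  f1 <- fit_population_model(ds, stage = "pk", covariates = "null_cl", seed = 1,
                             inits = f0$parlist,
                             control = list(iter.max = 300, eval.max = 600, rel.tol = 1e-5))
  expect_true(f0$convergence && f1$convergence)
  expect_equal(f1$ofv, f0$ofv, tolerance = 1e-4)
})

test_that("perturbing the residual SD away from its MLE worsens the fit", {
  ds <- small_dataset()
  ctrl <- list(iter.max = 300, eval.max = 600, rel.tol = 1e-5)
  free <- fit_population_model(ds, stage = "pk", covariates = character(0),
                               seed = 1, control = ctrl)
  sig_hat <- free$estimates$sigma_pk_add
  bumped <- fit_population_model(ds, stage = "pk", covariates = character(0),
                                 fixed = list(sigma_pk_add = 2 * sig_hat),
                                 inits = free$parlist, seed = 1, control = ctrl)
  expect_true(free$convergence && bumped$convergence)
  expect_gt(bumped$ofv, free$ofv)
})

test_that("bootstrap resampling is reproducible and reports convergence", {
  ds <- small_dataset()
  ctrl <- list(iter.max = 200, eval.max = 400, rel.tol = 1e-4)
  b1 <- bootstrap_ci(ds, reps = 2, max_retries = 1, seed = 3, stage = "pk",
                     covariates = character(0), control = ctrl)
  b2 <- bootstrap_ci(ds, reps = 2, max_retries = 1, seed = 3, stage = "pk",
                     covariates = character(0), control = ctrl)
  expect_identical(b1$table, b2$table)
  expect_true(b1$convergence_rate >= 0 && b1$convergence_rate <= 1)
  expect_true(all(c("parameter", "median", "lower", "upper") %in% names(b1$table)))
  expect_true(all(b1$table$lower <= b1$table$median + 1e-12))
})

test_that("vpc with a single replicate returns that replicate's percentiles", {
  ds <- small_dataset()
  v1 <- vpc_bands(ds, ref_model(), n_rep = 1, seed = 5)
  # the across-replicate envelope of one replicate collapses to a point
  expect_equal(v1$sim_p50_lo, v1$sim_p50_hi)
  expect_equal(v1$sim_p10_lo, v1$sim_p10_hi)
  expect_identical(v1, vpc_bands(ds, ref_model(), n_rep = 1, seed = 5))
})

test_that("vpc envelopes cover data simulated from the model itself", {
  ds <- small_dataset()
  v <- vpc_bands(ds, ref_model(), n_rep = 40, seed = 6)
  pk <- v[v$dvid == 1L, ]
  covered <- mean(pk$obs_p50 >= pk$sim_p50_lo & pk$obs_p50 <= pk$sim_p50_hi)
  expect_gt(covered, 0.7)
})
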