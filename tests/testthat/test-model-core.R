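test_that("covariate models reproduce the reported typical values", {
  m <- ref_model()
  # power model of eGFR on CL/F at the renal-function benchmarks
  expect_equal(round(typ_params(egfr = 100)$cl, 2), 12.66)
  expect_equal(round(typ_params(egfr = 75)$cl, 2), 8.61)
  expect_equal(round(typ_params(egfr = 45)$cl, 2), 4.34)
  # covariate at its reference leaves the population value untouched
  p_ref <- typ_params(egfr = 84.85)
  expect_equal(p_ref$cl, m$cl_pop)
  expect_equal(p_ref$ke1, 0.53)
  # proportional-exponential genotype model on ke1
  expect_equal(round(typ_params(oct2 = "GT")$ke1, 2), 0.05)
  expect_equal(typ_params(oct2 = "GT")$ke1, 0.53 * exp(-2.44))
  expect_equal(typ_params(oct2 = "TT")$ke1, 0.53 * exp(-2 * 2.44))
})

test_that("typical_parameters validates covariates", {
  m <- ref_model()
  expect_error(typical_parameters(m, list(egfr = NA, oct2 = "GG")), "missing")
  expect_error(typical_parameters(m, list(oct2 = "GG")), "missing")
  expect_error(typical_parameters(m, list(egfr = -5, oct2 = "GG")), "positive")
  expect_error(typical_parameters(m, list(egfr = 90, oct2 = "AG")), "genotype")
})

test_that("population_model enforces its invariants", {
  expect_error(population_model(cl_pop = -1), "positive")
  expect_error(population_model(e0_pop = 11), "0, 10")
  expect_error(population_model(imax = 0), "imax")
  expect_error(population_model(omega = c(v2 = 0.3)), "omega")
})

test_that("random effects transform parameters on the documented scales", {
  typ <- typ_params()
  # all-zero eta is the identity
  expect_identical(individual_parameters(typ, c(cl = 0, ka = 0)), typ)
  # log-normal construction
  p <- individual_parameters(typ, c(cl = log(2)))
  expect_equal(p$cl, 2 * typ$cl)
  expect_equal(p$v1, typ$v1)
  # logit-normal keeps E0 strictly inside the VAS bounds
  expect_lt(individual_parameters(typ, c(e0 = 10))$e0, 10)
  expect_gt(individual_parameters(typ, c(e0 = -10))$e0, 0)
  # no IIV exists on v2 / ke2 / ic50 / imax
  expect_error(individual_parameters(typ, c(v2 = 0.1)), "without IIV")
})

test_that("plasma profile respects dose, lag time and mass balance", {
  p <- typ_params()
  reg0 <- regimen(0, tau = 8, n_doses = 3)
  expect_true(all(plasma_profile(p, reg0, seq(0, 24, 0.5))$values == 0))
  reg <- regimen(300, tau = 24, n_doses = 1)
  # nothing is absorbed before first_dose_time + tlag (0.34 h)
  expect_equal(plasma_profile(p, reg, c(0.1, 0.2, 0.3))$values, c(0, 0, 0))
  expect_error(plasma_profile(p, reg, c(-1, 2)), "negative")
  # total exposure equals dose / clearance: AUC_0-inf = 300 / 10.16
  tt <- seq(0, 700, 0.05)
  auc <- pracma::trapz(tt, plasma_profile(p, reg, tt)$values)
  expect_equal(auc, 300 / 10.16, tolerance = 0.005)
})

test_that("closed-form and ODE plasma solutions agree", {
  reg <- regimen(300, tau = 8, n_doses = 6)
  tt <- seq(0, 48, 0.25)
  for (s in 1:5) {
    p <- random_params(s)
    a <- plasma_profile(p, reg, tt, method = "closed")$values
    b <- plasma_profile(p, reg, tt, method = "ode")$values
    expect_lt(max(abs(a - b)) / max(b), 1e-6)
  }
})

test_that("effect site reaches ke1/ke2-scaled steady state for constant input", {
  p <- typ_params()  # ke1 0.53, ke2 1
  tt <- seq(0, 15, 0.02)
  const <- time_profile(tt, rep(1, length(tt)))  # 1 mg/L = 1000 ng/mL
  ce <- effect_site_profile(p, const)
  # converged within 0.1% after 10 / ke2 hours
  expect_equal(ce$values[tt >= 10], rep(530, sum(tt >= 10)), tolerance = 1e-3)
})

test_that("effect site is linear in ke1 and zero when ke1 = 0", {
  typ <- typ_params()
  reg <- regimen(300, tau = 8, n_doses = 9)
  tt <- seq(0, 72, 0.02)
  cp <- plasma_profile(typ, reg, tt)
  half <- typ; half$ke1 <- typ$ke1 / 2
  zero <- typ; zero$ke1 <- 0
  ce1 <- effect_site_profile(typ, cp)$values
  ce2 <- effect_site_profile(half, cp)$values
  expect_equal(ce2, ce1 / 2, tolerance = 1e-10)
  expect_true(all(effect_site_profile(zero, cp)$values == 0))
  # exact-step integration agrees with the closed-form convolution (the
  # residual discrepancy is the grid's resolution of the absorption onset)
  ce_cf <- gabapkpd:::.ce_closed(typ, reg, tt)
  expect_lt(max(abs(ce1 - ce_cf)) / max(ce_cf), 1e-4)
})

test_that("Imax pain model hits its anchor points", {
  p <- typ_params()
  anchors <- time_profile(1:3, c(0, 263.11, 1e9))
  out <- pain_profile(p, anchors)
  expect_equal(out$score$values[1], 7.31)
  expect_equal(out$attenuation$values[1], 0)
  expect_equal(out$attenuation$values[2], 50)
  expect_equal(out$score$values[2], 7.31 / 2)
  expect_equal(out$attenuation$values[3], 100, tolerance = 1e-6)
})

test_that("attenuation is invariant to E0 when Imax = 1", {
  p1 <- typ_params()
  p2 <- individual_parameters(p1, c(e0 = 1.3))
  ce <- time_profile(seq(0, 8, 0.5), seq(0, 800, length.out = 17))
  expect_equal(pain_profile(p1, ce)$attenuation$values,
               pain_profile(p2, ce)$attenuation$values)
})
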