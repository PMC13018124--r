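test_that("renal stages carry the label eGFR bounds and frequencies", {
  s <- lapply(1:4, renal_stage)
  expect_equal(sapply(s, function(x) c(x$egfr_lower, x$egfr_upper)),
               matrix(c(90, 120, 60, 89, 30, 59, 15, 29), nrow = 2))
  expect_equal(sapply(s, `[[`, "tau"), c(8, 8, 12, 24))
  expect_error(renal_stage(5), "stage")
})

test_that("label regimens list the stage-specific doses over 5 weeks", {
  r1 <- label_regimens(1)
  expect_equal(sapply(r1, `[[`, "dose"), c(300, 400, 600, 900, 1200))
  expect_true(all(sapply(r1, `[[`, "tau") == 8))
  expect_true(all(sapply(r1, `[[`, "n_doses") == 105))
  r3 <- label_regimens(3)
  expect_equal(sapply(r3, `[[`, "dose"), c(200, 300, 400, 700))
  expect_true(all(sapply(r3, `[[`, "tau") == 12))
  r4 <- label_regimens(4)
  expect_equal(sapply(r4, `[[`, "dose"), c(200, 300, 400, 700))
  expect_true(all(sapply(r4, `[[`, "tau") == 24))
})

test_that("virtual cohorts respect stage bounds, genotype and seed", {
  co <- build_virtual_cohort(1, "GG", n = 50, seed = 9)
  expect_true(all(co$egfr >= 90 & co$egfr <= 120))
  expect_true(all(co$oct2 == "GG"))
  co_gt <- build_virtual_cohort(1, "GT", n = 50, seed = 9)
  expect_true(all(co_gt$oct2 == "GT"))
  expect_identical(co, build_virtual_cohort(1, "GG", n = 50, seed = 9))
  # same seed gives common random numbers: identical eta and uniform draws
  expect_equal(co$eta_cl, co_gt$eta_cl)
})

test_that("genotype changes the PK profile by exactly zero", {
  reg <- regimen(300, 8, n_doses = 105)
  gg <- simulate_scenario(build_virtual_cohort(1, "GG", 15, seed = 4), reg)
  gt <- simulate_scenario(build_virtual_cohort(1, "GT", 15, seed = 4), reg)
  expect_identical(gg$plasma, gt$plasma)
  # and attenuation of the slower-influx genotype never exceeds the wild type
  expect_true(all(gt$attenuation <= gg$attenuation + 1e-12))
})

test_that("doubling the dose doubles steady-state AUC (linear kinetics)", {
  co <- build_virtual_cohort(2, "GG", 10, seed = 6)
  m1 <- interval_metrics(simulate_scenario(co, regimen(300, 8, 105)))
  m2 <- interval_metrics(simulate_scenario(co, regimen(600, 8, 105)))
  expect_equal(m2$auc_tau, 2 * m1$auc_tau, tolerance = 1e-10)
  expect_equal(m2$cmax, 2 * m1$cmax, tolerance = 1e-10)
})

test_that("median AUC ratio across stages tracks the analytic clearance ratio", {
  n <- 150
  m1 <- interval_metrics(simulate_scenario(
    build_virtual_cohort(1, "GG", n, seed = 21), regimen(300, 8, 105)))
  m3 <- interval_metrics(simulate_scenario(
    build_virtual_cohort(3, "GG", n, seed = 21), regimen(300, 12, 70)))
  fold <- median(m3$auc_tau) / median(m1$auc_tau)
  analytic <- (105 / 44.5)^1.34  # median eGFR ratio under the power model
  expect_equal(fold, analytic, tolerance = 0.1)
})

fake_profiles <- function(times, att, plasma) {
  structure(list(times = times,
                 plasma = matrix(plasma, 1, length(times)),
                 ce = matrix(0, 1, length(times)),
                 attenuation = matrix(att, 1, length(times)),
                 cohort = data.frame(subject_id = 1L),
                 regimen = regimen(1, tau = diff(range(times)), n_doses = 1)),
            class = "scenario_profiles")
}

test_that("interval metrics compute trapezoid areas and threshold flags", {
  tt <- seq(0, 8, 0.1)
  m <- interval_metrics(fake_profiles(tt, rep(55, length(tt)), rep(2, length(tt))))
  expect_equal(m$auc_tau, 16)
  expect_equal(m$cmax, 2)
  expect_equal(m$auec_tau, 8 * 55)
  expect_equal(m$max_attenuation, 55)
  expect_equal(m$category, "substantial")
  expect_true(m$pta_flag)
  # attenuation above 50% for exactly 6 of 8 hours (75% < 80%) fails the target
  att <- ifelse(tt <= 6, 60, 40)
  att[tt == 6] <- 60
  m2 <- interval_metrics(fake_profiles(tt, att, rep(1, length(tt))))
  expect_false(m2$pta_flag)
  expect_equal(m2$category, "substantial")  # max attenuation still 60
  # grid must span the dosing interval
  expect_error(interval_metrics(fake_profiles(tt, rep(1, length(tt)),
                                              rep(1, length(tt))), tau = 12),
               "interval")
})

test_that("response categories split at 30 and 50 percent maximum attenuation", {
  tt <- seq(0, 8, 0.5)
  cats <- vapply(c(10, 35, 75), function(a)
    interval_metrics(fake_profiles(tt, rep(a, length(tt)), rep(1, length(tt))))$category, "")
  expect_equal(cats, c("minimal", "moderate", "substantial"))
})

test_that("cohort summaries use linear-interpolation percentiles", {
  tt <- seq(0, 8, 1)
  metrics <- do.call(rbind, lapply(1:100, function(i) {
    m <- interval_metrics(fake_profiles(tt, rep(40, 9), rep(i, 9)))
    m$subject_id <- i
    m
  }))
  s <- summarize_cohort(metrics)
  expect_equal(s$quantiles["cmax", "median"], 50.5)
  expect_equal(s$quantiles["cmax", "p10"], 10.9)
  expect_equal(s$quantiles["cmax", "p90"], 90.1)
  expect_equal(unname(s$category_pct["moderate"]), 100)
  expect_equal(s$pta_pct, 0)
})

test_that("PTA is nondecreasing in dose under common random numbers", {
  co <- build_virtual_cohort(1, "GG", 60, seed = 13)
  pta <- vapply(c(300, 600, 900), function(d)
    summarize_cohort(interval_metrics(simulate_scenario(co, regimen(d, 8, 105))))$pta_pct, 0)
  expect_true(all(diff(pta) >= 0))
})
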