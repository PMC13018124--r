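test_that("sampled covariates match the cohort summary statistics", {
  cov <- sample_covariates(1e4, seed = 8)
  expect_equal(mean(cov$egfr_true), 90.29, tolerance = 0.02)
  expect_equal(mean(cov$age), 53, tolerance = 0.02)
  expect_equal(mean(cov$weight), 81.97, tolerance = 0.02)
  expect_lt(abs(mean(is.na(cov$egfr)) - 0.12), 0.015)
  expect_lt(abs(mean(cov$sex == "F") - 53 / 94), 0.02)
  expect_identical(cov, sample_covariates(1e4, seed = 8))
  # missingness hides the record but the true physiology remains available
  expect_true(all(!is.na(cov$egfr_true)))
})

test_that("genotype assignment reproduces counts exactly at the cohort size", {
  g <- assign_genotypes(94, c(GG = 79, GT = 15, TT = 0), seed = 2)
  expect_equal(unname(table(factor(g, c("GG", "GT", "TT")))), c(79L, 15L, 0L),
               ignore_attr = TRUE)
  expect_true(all(assign_genotypes(50, c(CC = 100, CT = 0, TT = 0), seed = 1) == "CC"))
  expect_identical(assign_genotypes(30, c(CC = 42, CT = 39, TT = 13), seed = 5),
                   assign_genotypes(30, c(CC = 42, CT = 39, TT = 13), seed = 5))
})

test_that("allele frequencies and Hardy-Weinberg tests match the cohort genetics", {
  p_oct2 <- allele_frequencies(c(GG = 79, GT = 15, TT = 0))
  expect_equal(round(unname(p_oct2), 2), c(0.92, 0.08))
  p_octn1 <- allele_frequencies(c(CC = 42, CT = 39, TT = 13))
  expect_equal(round(unname(p_octn1), 2), c(0.65, 0.35))
  expect_equal(unname(allele_frequencies(c(10, 0, 0))["p"]), 1)
  expect_error(allele_frequencies(c(0, 0, 0)), "zero")

  h1 <- hwe_chi_square(c(GG = 79, GT = 15, TT = 0))
  expect_equal(round(unname(h1), 2), c(0.71, 0.40))
  h2 <- hwe_chi_square(c(CC = 42, CT = 39, TT = 13))
  expect_equal(round(unname(h2), 2), c(0.65, 0.42))
  # counts in exact equilibrium (p = 0.7, n = 100) give chi-square zero
  expect_equal(unname(hwe_chi_square(c(49, 42, 9))["chi2"]), 0, tolerance = 1e-12)
})

test_that("study 1 dataset follows the rich single-dose design", {
  ds <- generate_study_dataset(study_design("study1"), seed = 3)
  expect_equal(length(unique(ds$ID)), 29L)
  doses <- ds[ds$EVID == 1L, ]
  expect_equal(nrow(doses), 29L)
  expect_true(all(doses$AMT == 300))
  expect_equal(sum(ds$EVID == 0L & ds$DVID == 1L), 29L * 10L)
  expect_equal(sum(ds$EVID == 0L & ds$DVID == 2L), 29L * 9L)
  expect_identical(ds, generate_study_dataset(study_design("study1"), seed = 3))
})

test_that("pooled dataset hits the published record-count targets", {
  ds <- generate_pooled_dataset(seed = 17)
  expect_equal(length(unique(ds$ID)), 94L)
  n_pk <- sum(ds$EVID == 0L & ds$DVID == 1L)
  n_pd <- sum(ds$EVID == 0L & ds$DVID == 2L)
  expect_lt(abs(n_pk - 568) / 568, 0.10)
  expect_lt(abs(n_pd - 392) / 392, 0.10)
  # pain scores live on the bounded VAS scale, never censored
  pd <- ds[ds$EVID == 0L & ds$DVID == 2L, ]
  expect_true(all(pd$DV >= 0 & pd$DV <= 10))
  expect_true(all(pd$CENS == 0L))
})

test_that("the BLQ fraction of pooled plasma records is near 9 percent", {
  frac <- vapply(c(17, 23), function(s) {
    ds <- generate_pooled_dataset(seed = s)
    pk <- ds[ds$EVID == 0L & ds$DVID == 1L, ]
    mean(pk$CENS)
  }, 0)
  expect_true(all(abs(frac - 0.0915) < 0.03))
})

test_that("generated datasets survive a write/read round trip", {
  ds <- generate_study_dataset(study_design("study1"), seed = 5)
  path <- tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_equal(back[, names(ds)], ds, tolerance = 1e-12, ignore_attr = TRUE)
})
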