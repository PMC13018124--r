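## Synthetic study-like data: covariate sampling, genotype assignment,
## observation dataset generation, and cohort-genetics statistics.

#' Study design templates
#'
#' Two designs emulating the pooled clinical datasets. `study1`: 29 subjects,
#' one 300 mg oral dose, rich PK sampling with concurrent VAS pain scores.
#' `study2`: 65 subjects on multiple dosing (total daily dose 600-3600 mg
#' split TID) observed sparsely at steady state. Published information fixes
#' only the subject counts, dose ranges and aggregate record counts (~568
#' plasma, ~392 pain observations, ~9% of plasma records below the 0.2 ug/mL
#' LLOQ); the sampling schedules here are synthetic conventions chosen to
#' land on those totals, not reported facts.
#'
#' @param label `"study1"` or `"study2"`
#' @param n_subjects optional override of the design's cohort size (the
#'   defaults are the published study sizes; smaller values give
#'   reduced-scale replicates for simulation experiments)
#' @return a `study_design` list
#' @export
study_design <- function(label = c("study1", "study2"), n_subjects = NULL) {
  label <- match.arg(label)
  d <- if (label == "study1") {
    list(label = "study1", n_subjects = 29L,
         dose = 300, tau = NA_real_, n_doses = 1L,
         pk_times = c(0, 0.5, 1, 2, 3, 4, 6, 8, 10, 12),
         pd_times = c(0, 1, 2, 3, 4, 6, 8, 10, 12),
         lloq = 0.2)
  } else {
    list(label = "study2", n_subjects = 65L,
         daily_doses = c(600, 900, 1200, 1800, 2400, 3600),
         tau = 8, days = 14L,
         n_pk_range = c(3L, 5L), n_pd = 2L,
         lloq = 0.2)
  }
  if (!is.null(n_subjects)) {
    stopifnot(n_subjects >= 1)
    d$n_subjects <- as.integer(n_subjects)
  }
  structure(d, class = "study_design")
}

#' Sample subject covariates
#'
#' Draws demographics from truncated normal distributions matching the pooled
#' cohort summaries: age 53 +/- 11 y (bounds 18-90), weight 81.97 +/- 17.34
#' kg (40-160), serum creatinine 0.92 +/- 0.41 mg/dL (0.3-3), eGFR 90.29 +/-
#' 22.79 mL/min/1.73 m2 (15-150); sex is Bernoulli with the observed 53:41
#' female:male split. A fraction of subjects (default 12%) has missing serum
#' creatinine and hence missing recorded eGFR; the generator still carries
#' the true (sampled) eGFR for simulation, mirroring how physiology exists
#' whether or not it was measured.
#'
#' @param n number of subjects
#' @param seed integer seed
#' @param missing_frac fraction with missing SCr/eGFR records
#' @return data.frame: subject_id, age, weight, sex, serum_creatinine, egfr
#'   (recorded, NA when missing), egfr_true
#' @export
sample_covariates <- function(n, seed, missing_frac = 0.12) {
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  rtnorm <- function(n, mean, sd, lo, hi) {
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x < lo | x > hi))
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
  }
  age <- rtnorm(n, 53, 11, 18, 90)
  wt <- rtnorm(n, 81.97, 17.34, 40, 160)
  scr <- rtnorm(n, 0.92, 0.41, 0.3, 3)
  egfr <- rtnorm(n, 90.29, 22.79, 15, 150)
  sex <- ifelse(stats::runif(n) < 53 / 94, "F", "M")
  miss <- stats::runif(n) < missing_frac
  data.frame(subject_id = seq_len(n), age = age, weight = wt, sex = sex,
             serum_creatinine = ifelse(miss, NA_real_, scr),
             egfr = ifelse(miss, NA_real_, egfr),
             egfr_true = egfr)
}

#' Assign genotypes from observed counts
#'
#' When `n` equals the total of `counts` the genotype labels are a random
#' permutation of exactly those counts (sampling without replacement, so the
#' cohort reproduces the printed counts exactly); otherwise labels are drawn
#' multinomially with the count frequencies.
#'
#' @param n number of subjects
#' @param counts named integer vector of genotype counts, in the order
#'   homozygous reference, heterozygous, homozygous variant (e.g.
#'   `c(GG = 79, GT = 15, TT = 0)`)
#' @param seed integer seed
#' @return character vector of genotype labels
#' @export
assign_genotypes <- function(n, counts, seed) {
  stopifnot(length(counts) == 3L, all(counts >= 0), sum(counts) > 0,
            !is.null(names(counts)))
  set.seed(as.integer(seed))
  if (n == sum(counts)) {
    sample(rep(names(counts), times = counts))
  } else {
    sample(names(counts), n, replace = TRUE, prob = counts / sum(counts))
  }
}

#' Allele frequencies from genotype counts
#'
#' For a biallelic locus with counts (hom ref, het, hom variant),
#' `p = (2 * hom_ref + het) / (2 * total)` and `q = 1 - p`.
#'
#' @param counts genotype counts, length 3 in the order above
#' @return named numeric `c(p = ..., q = ...)`
#' @examples
#' allele_frequencies(c(GG = 79, GT = 15, TT = 0))  # p = 0.92, q = 0.08
#' @export
allele_frequencies <- function(counts) {
  stopifnot(length(counts) == 3L, all(counts >= 0))
  total <- sum(counts)
  if (total == 0) stop("allele_frequencies: total genotype count is zero")
  p <- (2 * counts[[1]] + counts[[2]]) / (2 * total)
  c(p = p, q = 1 - p)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson chi-square of observed genotype counts against Hardy-Weinberg
#' expectations (n p^2, 2 n p q, n q^2) with allele frequencies estimated
#' from the same counts; 1 degree of freedom. A monomorphic locus (q = 0)
#' returns chi-square 0 by convention (the expectations reproduce the
#' observations exactly).
#'
#' @param counts genotype counts, length 3 (hom ref, het, hom variant)
#' @return named numeric `c(chi2 = ..., p_value = ...)`
#' @examples
#' hwe_chi_square(c(GG = 79, GT = 15, TT = 0))  # chi2 0.71, p 0.40
#' @export
hwe_chi_square <- function(counts) {
  stopifnot(length(counts) == 3L, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("hwe_chi_square: total genotype count is zero")
  p <- allele_frequencies(counts)[["p"]]
  q <- 1 - p
  expected <- n * c(p^2, 2 * p * q, q^2)
  nz <- expected > 0
  chi2 <- sum((counts[nz] - expected[nz])^2 / expected[nz])
  c(chi2 = chi2, p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

## Default genotype counts observed in the pooled cohort (n = 94).
oct2_counts <- function() c(GG = 79L, GT = 15L, TT = 0L)
octn1_counts <- function() c(CC = 42L, CT = 39L, TT = 13L)

#' Generate a study-like observation dataset
#'
#' Simulates a long-format NONMEM-style dataset under a [study_design()]:
#' dosing records, plasma concentrations with additive residual error and
#' left-censoring below the LLOQ, and VAS pain scores with combined residual
#' error clamped to the 0-10 scale. Covariates come from
#' [sample_covariates()] (the true sampled eGFR drives the kinetics even when
#' the recorded value is missing) and genotypes from [assign_genotypes()]
#' at the pooled-cohort frequencies.
#'
#' @param design a [study_design()]
#' @param model a [population_model()]
#' @param seed integer seed; all internal draws derive from it
#' @param first_id subject IDs start here (lets two studies pool without
#'   collisions)
#' @return data.frame in the observation-dataset schema of [read_dataset()],
#'   plus a STUDY column
#' @export
generate_study_dataset <- function(design, model = population_model(), seed = 1,
                                   first_id = 1L) {
  stopifnot(inherits(design, "study_design"))
  validate_population_model(model)
  n <- design$n_subjects
  cov <- sample_covariates(n, derive_seed(seed, paste0(design$label, "_cov")))
  oct2 <- assign_genotypes(n, oct2_counts(), derive_seed(seed, paste0(design$label, "_oct2")))
  octn1 <- assign_genotypes(n, octn1_counts(), derive_seed(seed, paste0(design$label, "_octn1")))
  eta <- sample_random_effects(model$omega, n, derive_seed(seed, paste0(design$label, "_eta")))
  rspec <- residual_spec(model$sigma_pk_add, model$sigma_pd_add, model$sigma_pd_prop)
  set.seed(derive_seed(seed, paste0(design$label, "_sched")))

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (design$label == "study1") {
      reg <- regimen(design$dose, tau = 24, n_doses = 1L)
      pk_t <- design$pk_times
      pd_t <- design$pd_times
    } else {
      daily <- sample(design$daily_doses, 1L)
      reg <- regimen(daily / 3, tau = design$tau,
                     n_doses = as.integer(design$days * 24 / design$tau))
      Tend <- regimen_horizon(reg)
      n_pk <- sample(seq(design$n_pk_range[1], design$n_pk_range[2]), 1L)
      pk_t <- sort(round(stats::runif(n_pk, Tend - reg$tau, Tend), 2))
      pd_t <- sort(round(stats::runif(design$n_pd, Tend - reg$tau, Tend), 2))
    }
    typ <- typical_parameters(model, list(egfr = cov$egfr_true[i], oct2 = oct2[i]))
    e <- eta[i, ]
    p <- individual_parameters(typ, e)
    all_t <- sort(unique(c(pk_t, pd_t)))
    grid <- sort(unique(c(seq(0, max(all_t), by = 0.1), all_t)))
    grid <- grid[grid <= max(all_t)]
    cp <- plasma_profile(p, reg, grid[grid >= 0])
    ce <- effect_site_profile(p, cp)
    pk_pred <- cp$values[match(pk_t, cp$times)]
    ce_pd <- ce$values[match(pd_t, ce$times)]
    pd_pred <- p$e0 * (1 - p$imax * ce_pd / (p$ic50 + ce_pd))
    pk_obs <- apply_residual_error(pk_pred, rspec, "PK",
                                   derive_seed(seed, paste0(design$label, "_epk", i)))
    pd_obs <- apply_residual_error(pd_pred, rspec, "PD",
                                   derive_seed(seed, paste0(design$label, "_epd", i)))
    cb <- censor_blq(pk_obs, design$lloq)
    id <- first_id + i - 1L
    base <- data.frame(ID = id, EGFR = cov$egfr[i], OCT2 = oct2[i],
                       OCTN1 = octn1[i], AGE = cov$age[i], WT = cov$weight[i],
                       SEX = cov$sex[i], STUDY = design$label)
    dose_rows <- cbind(data.frame(TIME = dose_times(reg), EVID = 1L,
                                  AMT = reg$dose, DVID = NA_integer_,
                                  DV = NA_real_, CENS = 0L,
                                  LLOQ = design$lloq), base)
    pk_rows <- cbind(data.frame(TIME = pk_t, EVID = 0L, AMT = NA_real_,
                                DVID = 1L, DV = cb$value, CENS = cb$cens,
                                LLOQ = design$lloq), base)
    pd_rows <- cbind(data.frame(TIME = pd_t, EVID = 0L, AMT = NA_real_,
                                DVID = 2L, DV = pd_obs, CENS = 0L,
                                LLOQ = design$lloq), base)
    sub <- rbind(dose_rows, pk_rows, pd_rows)
    ## stable clinical ordering: by time, doses before observations at ties
    sub <- sub[order(sub$TIME, -sub$EVID, sub$DVID), ]
    rows[[i]] <- sub
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  cols <- c("ID", "TIME", "EVID", "AMT", "DVID", "DV", "CENS", "LLOQ",
            "EGFR", "OCT2", "OCTN1", "AGE", "WT", "SEX", "STUDY")
  out[, cols]
}

#' Generate the pooled two-study dataset
#'
#' Convenience wrapper: study 1 and study 2 generated from one seed and
#' row-bound with non-overlapping subject IDs.
#'
#' @param model a [population_model()]
#' @param seed integer seed
#' @return pooled observation data.frame
#' @export
generate_pooled_dataset <- function(model = population_model(), seed = 1) {
  d1 <- generate_study_dataset(study_design("study1"), model, seed, first_id = 1L)
  d2 <- generate_study_dataset(study_design("study2"), model, seed,
                               first_id = study_design("study1")$n_subjects + 1L)
  rbind(d1, d2)
}
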