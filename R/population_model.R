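#' Population PK/PD parameter set for gabapentin
#'
#' Constructs the population model object holding fixed effects, covariate
#' coefficients, inter-individual variability (IIV) standard deviations and
#' residual-error parameters. Defaults are the final joint-model estimates:
#' two-compartment oral PK (tlag, ka, CL/F, V1/F, Q, V2/F) with eGFR as a
#' power covariate on CL/F (reference 84.85 mL/min/1.73 m2), and an
#' effect-compartment Imax pain model (ke1, ke2 fixed at 1/h, E0, IC50 fixed
#' at 263.11 ng/mL, Imax fixed at 1) with the OCT2 (SLC22A2 c.808G>T)
#' genotype as a proportional-exponential covariate on ke1.
#'
#' Units: times h, rate constants 1/h, clearances L/h, volumes L, plasma
#' concentrations mg/L (numerically identical to ug/mL), effect-site
#' concentration and IC50 ng/mL, pain score VAS units on 0-10.
#'
#' @param tlag_pop absorption lag time (h)
#' @param ka_pop first-order absorption rate constant (1/h)
#' @param cl_pop apparent clearance CL/F (L/h) at the reference eGFR
#' @param v1_pop apparent central volume V1/F (L)
#' @param q_pop apparent intercompartmental clearance Q/F (L/h)
#' @param v2_pop apparent peripheral volume V2/F (L)
#' @param ke1_pop effect-site influx rate constant (1/h) for the GG genotype
#' @param ke2 effect-site efflux rate constant (1/h); fixed in the final model
#' @param e0_pop baseline VAS pain score, bounded in (0, 10)
#' @param ic50 effect-site concentration of half-maximal inhibition (ng/mL)
#' @param imax maximal fractional inhibition, in (0, 1]
#' @param beta_egfr_cl power exponent of eGFR on CL/F
#' @param egfr_ref reference eGFR (mL/min/1.73 m2)
#' @param beta_oct2_ke1 proportional-exponential genotype coefficient on ke1
#'   (per copy of the T allele)
#' @param omega named numeric vector of IIV standard deviations; names must be
#'   a subset of `c("tlag","ka","cl","v1","q","ke1","e0")` (parameters with no
#'   estimated IIV carry none)
#' @param sigma_pk_add additive PK residual SD (mg/L)
#' @param sigma_pd_add additive PD residual SD (VAS units)
#' @param sigma_pd_prop proportional PD residual coefficient
#' @return an object of class `population_model`
#' @examples
#' m <- population_model()
#' typical_parameters(m, list(egfr = 100, oct2 = "GG"))$cl
#' @export
population_model <- function(tlag_pop = 0.34, ka_pop = 0.14, cl_pop = 10.16,
                             v1_pop = 18.16, q_pop = 6.58, v2_pop = 357.67,
                             ke1_pop = 0.53, ke2 = 1, e0_pop = 7.31,
                             ic50 = 263.11, imax = 1,
                             beta_egfr_cl = 1.34, egfr_ref = 84.85,
                             beta_oct2_ke1 = -2.44,
                             omega = c(tlag = 0.52, ka = 0.15, cl = 0.46,
                                       v1 = 0.54, q = 0.64, ke1 = 2.11,
                                       e0 = 0.98),
                             sigma_pk_add = 0.19,
                             sigma_pd_add = 0.52, sigma_pd_prop = 0.30) {
  m <- list(tlag_pop = tlag_pop, ka_pop = ka_pop, cl_pop = cl_pop,
            v1_pop = v1_pop, q_pop = q_pop, v2_pop = v2_pop,
            ke1_pop = ke1_pop, ke2 = ke2, e0_pop = e0_pop,
            ic50 = ic50, imax = imax,
            beta_egfr_cl = beta_egfr_cl, egfr_ref = egfr_ref,
            beta_oct2_ke1 = beta_oct2_ke1,
            omega = omega,
            sigma_pk_add = sigma_pk_add,
            sigma_pd_add = sigma_pd_add, sigma_pd_prop = sigma_pd_prop)
  class(m) <- "population_model"
  validate_population_model(m)
  m
}

#' @rdname population_model
#' @param x a `population_model`
#' @export
validate_population_model <- function(x) {
  stopifnot(inherits(x, "population_model"))
  pos <- c("tlag_pop", "ka_pop", "cl_pop", "v1_pop", "q_pop", "v2_pop",
           "ke1_pop", "ke2", "ic50", "egfr_ref")
  for (nm in pos)
    if (!is.numeric(x[[nm]]) || length(x[[nm]]) != 1L || x[[nm]] <= 0)
      stop("population_model: '", nm, "' must be a positive scalar")
  if (x$e0_pop <= 0 || x$e0_pop >= 10)
    stop("population_model: 'e0_pop' must lie strictly inside (0, 10)")
  if (x$imax <= 0 || x$imax > 1)
    stop("population_model: 'imax' must lie in (0, 1]")
  if (is.null(names(x$omega)) ||
      !all(names(x$omega) %in% iiv_parameters()))
    stop("population_model: omega names must be a subset of {",
         paste(iiv_parameters(), collapse = ", "), "}")
  if (any(x$omega < 0)) stop("population_model: omega values must be >= 0")
  for (nm in c("sigma_pk_add", "sigma_pd_add", "sigma_pd_prop"))
    if (x[[nm]] < 0) stop("population_model: '", nm, "' must be >= 0")
  invisible(x)
}

#' Parameters carrying inter-individual variability
#'
#' The model estimates IIV on these parameters only; V2/F, ke2, IC50 and Imax
#' carry none. `e0` uses a logit-normal random effect, the rest log-normal.
#' @return character vector of parameter names
#' @export
iiv_parameters <- function() c("tlag", "ka", "cl", "v1", "q", "ke1", "e0")

#' @export
print.population_model <- function(x, ...) {
  cat("Population PK/PD model (gabapentin, oral IR)\n")
  cat(sprintf("  PK: tlag %.3g h, ka %.3g 1/h, CL/F %.4g L/h, V1/F %.4g L, Q %.4g L/h, V2/F %.4g L\n",
              x$tlag_pop, x$ka_pop, x$cl_pop, x$v1_pop, x$q_pop, x$v2_pop))
  cat(sprintf("  covariates: eGFR on CL/F (power %.3g, ref %.4g); OCT2 on ke1 (beta %.3g)\n",
              x$beta_egfr_cl, x$egfr_ref, x$beta_oct2_ke1))
  cat(sprintf("  PD: ke1 %.3g 1/h, ke2 %.3g 1/h, E0 %.3g, IC50 %.5g ng/mL, Imax %.3g\n",
              x$ke1_pop, x$ke2, x$e0_pop, x$ic50, x$imax))
  cat("  IIV SD:", paste(sprintf("%s %.3g", names(x$omega), x$omega), collapse = ", "), "\n")
  cat(sprintf("  residual: PK additive %.3g mg/L; PD additive %.3g + proportional %.3g\n",
              x$sigma_pk_add, x$sigma_pd_add, x$sigma_pd_prop))
  invisible(x)
}

#' Numeric genotype code for a biallelic transporter variant
#'
#' The covariate model counts copies of the variant allele: for SLC22A2
#' c.808G>T, GG = 0 (reference), GT = 1, TT = 2; for SLC22A4 c.1507C>T,
#' CC = 0, CT = 1, TT = 2.
#'
#' @param genotype character vector of genotype labels
#' @param locus `"oct2"` (alleles G/T) or `"octn1"` (alleles C/T)
#' @return integer vector of variant-allele counts
#' @export
genotype_code <- function(genotype, locus = c("oct2", "octn1")) {
  locus <- match.arg(locus)
  levels <- if (locus == "oct2") c("GG", "GT", "TT") else c("CC", "CT", "TT")
  idx <- match(genotype, levels)
  if (anyNA(idx))
    stop("unknown ", locus, " genotype code(s): ",
         paste(unique(genotype[is.na(idx)]), collapse = ", "),
         " (expected ", paste(levels, collapse = "/"), ")")
  idx - 1L
}

#' Typical individual parameters from covariates
#'
#' Applies the covariate models at zero random effects: the power model
#' `CL_i = CL_pop * (eGFR / eGFR_ref)^beta` for renal function and the
#' proportional-exponential model `ke1_i = ke1_pop * exp(beta * g)` where `g`
#' counts T alleles of SLC22A2 c.808G>T (GG = 0, GT = 1, TT = 2). All other
#' parameters equal their population values.
#'
#' @param model a [population_model()]
#' @param cov list or one-row data.frame with at least `egfr` (mL/min/1.73 m2,
#'   must be present and positive -- impute before calling) and `oct2`
#'   (genotype label `"GG"`, `"GT"` or `"TT"`)
#' @return an `individual_parameters` list: tlag, ka, cl, v1, q, v2, ke1, ke2,
#'   e0, ic50, imax
#' @examples
#' m <- population_model()
#' typical_parameters(m, list(egfr = 100, oct2 = "GG"))$cl  # 12.66 L/h
#' typical_parameters(m, list(egfr = 45, oct2 = "GG"))$cl   # 4.34 L/h
#' @export
typical_parameters <- function(model, cov) {
  validate_population_model(model)
  egfr <- cov$egfr
  if (is.null(egfr) || length(egfr) != 1L || is.na(egfr))
    stop("typical_parameters: eGFR is missing; impute it before computing individual parameters")
  if (egfr <= 0) stop("typical_parameters: eGFR must be positive")
  g <- genotype_code(as.character(cov$oct2), "oct2")
  p <- list(
    tlag = model$tlag_pop,
    ka   = model$ka_pop,
    cl   = model$cl_pop * (egfr / model$egfr_ref)^model$beta_egfr_cl,
    v1   = model$v1_pop,
    q    = model$q_pop,
    v2   = model$v2_pop,
    ke1  = model$ke1_pop * exp(model$beta_oct2_ke1 * g),
    ke2  = model$ke2,
    e0   = model$e0_pop,
    ic50 = model$ic50,
    imax = model$imax
  )
  class(p) <- "individual_parameters"
  p
}

#' Realized individual parameters from random effects
#'
#' Parameters with IIV are log-normal, `p_i = p_typ * exp(eta)`, except the
#' baseline pain score E0, which is logit-normal on the bounded 0-10 VAS
#' scale: `E0_i = 10 * plogis(qlogis(E0_typ / 10) + eta_e0)`, keeping every
#' realization strictly inside (0, 10).
#'
#' @param typical an `individual_parameters` object from
#'   [typical_parameters()]
#' @param eta named numeric vector of random effects; names must be a subset
#'   of [iiv_parameters()] -- supplying an eta for a parameter without IIV
#'   (v2, ke2, ic50, imax) is an error
#' @return an `individual_parameters` object
#' @export
individual_parameters <- function(typical, eta = numeric(0)) {
  stopifnot(inherits(typical, "individual_parameters"))
  if (length(eta)) {
    bad <- setdiff(names(eta), iiv_parameters())
    if (length(bad) || is.null(names(eta)))
      stop("individual_parameters: eta supplied for parameter(s) without IIV: ",
           paste(bad, collapse = ", "))
  }
  p <- typical
  for (nm in setdiff(names(eta), "e0")) p[[nm]] <- typical[[nm]] * exp(eta[[nm]])
  if ("e0" %in% names(eta))
    p$e0 <- 10 * stats::plogis(stats::qlogis(typical$e0 / 10) + eta[["e0"]])
  p
}

#' @export
print.individual_parameters <- function(x, ...) {
  cat("Individual PK/PD parameters:\n")
  cat(sprintf("  tlag %.3g h | ka %.3g 1/h | CL/F %.4g L/h | V1/F %.4g L | Q %.4g L/h | V2/F %.4g L\n",
              x$tlag, x$ka, x$cl, x$v1, x$q, x$v2))
  cat(sprintf("  ke1 %.3g 1/h | ke2 %.3g 1/h | E0 %.3g | IC50 %.5g ng/mL | Imax %.3g\n",
              x$ke1, x$ke2, x$e0, x$ic50, x$imax))
  invisible(x)
}
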