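---
title: "Methods: joint population PK/PD modelling of gabapentin with renal function and OCT2 genotype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint population PK/PD modelling of gabapentin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gabapkpd)
```

## The model

Gabapentin is an orally dosed analgesic whose clearance is almost entirely
renal and whose analgesic effect lags behind plasma concentration because the
drug must first reach its central-nervous-system target. `gabapkpd`
implements a joint population pharmacokinetic/pharmacodynamic model capturing
both features, plus the pharmacogenetic mechanism that makes some patients
poor responders: the organic cation transporter OCT2 (*SLC22A2* c.808G>T)
carries gabapentin across the blood--brain barrier, and reduced-function
variants slow drug delivery to the effect site without changing systemic
exposure.

**Pharmacokinetics.** A two-compartment model with first-order absorption,
absorption lag time and linear elimination. Parameters are apparent oral
quantities (CL/F, V1/F, Q/F, V2/F). Renal function enters as a power
covariate on clearance,

$$\mathrm{CL}_i = \mathrm{CL}_{pop}\,(\mathrm{eGFR}_i / 84.85)^{\beta},$$

with the reference 84.85 mL/min/1.73 m^2 being the weighted mean of the
modelled cohort and $\beta = 1.34$. Plasma concentration is central amount
over V1/F in mg/L, numerically identical to the assay's ug/mL scale.

**Pharmacodynamics.** VAS pain score (0--10) follows an inhibitory Imax
model driven by the concentration $C_e$ in a hypothetical effect
compartment:

$$\frac{dC_e}{dt} = k_{e1} C_p - k_{e2} C_e, \qquad
  E(t) = E_0\left(1 - \frac{I_{max} C_e}{IC_{50} + C_e}\right).$$

$I_{max}$ is fixed at 1 (full inhibition), $k_{e2}$ at 1/h and $IC_{50}$ at
263.11 ng/mL, the final-model conventions; attenuation is the percent
reduction from baseline, $100\,C_e/(IC_{50}+C_e)$ under full inhibition,
and is then independent of $E_0$. The genotype acts on the influx rate by a
proportional-exponential model, $k_{e1,i} = k_{e1,pop}\,e^{\beta_g g_i}$
with $g_i$ the count of T alleles ($\beta_g = -2.44$: heterozygotes have a
roughly ten-fold slower influx, 0.53 vs 0.05 1/h).

Two deliberate unit/parameterization choices:

* Plasma is carried in mg/L; the conversion to ng/mL (x1000) happens once,
  at the PK-to-PD link, because IC50 is reported in ng/mL.
* $C_e$ keeps the steady-state gain $k_{e1}/k_{e2}$ -- it is **not**
  normalized to unit gain. The genotype mechanism operates through this
  gain: halving $k_{e1}$ halves steady-state $C_e$ and therefore reduces
  attenuation. A unit-gain parameterization would reduce the genotype
  effect to a pure delay and could not reproduce the reported response
  differences; the magnitude of the fitted IC50 is only consistent with
  the gain interpretation, which we adopt (the alternative was examined
  and rejected at design time).

**Variability.** Random effects are log-normal on all disposition and
rate parameters with estimated inter-individual variability (tlag, ka, CL,
V1, Q, ke1) and logit-normal on $E_0$ so realizations stay strictly inside
the 0--10 VAS bounds; the covariance is diagonal. Residual error is
additive for plasma (SD 0.19 mg/L) and combined for pain scores
(SD $= a + b f$, the "combined1" convention, $a = 0.52$, $b = 0.30$; a
`combined2` switch, SD $=\sqrt{a^2+b^2f^2}$, is provided). Simulated VAS
observations are clamped to [0, 10]: the instrument cannot report outside
its scale.

## Kinetic computation

Multi-dose profiles use the closed-form tri-exponential solution of the
two-compartment oral model, superposed over doses, with each dose shifted by
the lag time; the effect-site concentration is the exact convolution of
those exponentials with the effect-compartment impulse response, so no ODE
integration is needed in the simulation path. An adaptive ODE route
(`deSolve::lsoda`, rtol 1e-8) implements the same kinetics independently;
the two agree to better than 1e-6 relative and the ODE route doubles as a
fallback if an absorption rate collides with a disposition exponent (the
closed form is singular there; the closed-form path nudges ka by a relative
1e-7 when the collision is within 1e-8). For tabulated plasma input,
`effect_site_profile()` advances the linear ODE by its exact one-step update
under piecewise-linear interpolation, so its error is set by the input grid
alone. Metric grids use 0.1 h resolution: the shortest model time constant
is $1/k_{e2} = 1$ h, so trapezoid error at 0.1 h is negligible.

## Trial simulation

Virtual cohorts of 200 subjects per renal stage draw eGFR uniformly within
the stage bounds (stage 1: 90--120, stage 2: 60--89, stage 3: 30--59,
stage 4: 15--29 mL/min/1.73 m^2) and carry one genotype each (100%
frequency within a subgroup, so genotype contrasts are between matched
cohorts). Label regimens are 300/400/600/900/1200 mg TID for stages 1--2,
200/300/400/700 mg BID for stage 3 and the same doses QD for stage 4;
dosing is equally spaced (every 8/12/24 h, first dose at t = 0) since only
frequencies are prescribed. A 5-week course guarantees PK and PD steady
state (the terminal half-life is ~63 h), and all metrics are evaluated on
the final dosing interval from individual model predictions *without*
residual error -- exposure/response targets are properties of the smooth
individual profiles, and metrics on noisy virtual observations would not
estimate them.

Per-subject metrics: trapezoid AUC and Cmax of plasma, trapezoid AUEC and
maximum of attenuation, the response category (minimal < 30%, moderate
30--50%, substantial >= 50% maximum attenuation), and the sustained-relief
flag (attenuation >= 50% for >= 80% of the interval, with time above
threshold measured exactly on the piecewise-linear curve). Cohort summaries
report medians with 10th/90th percentiles using linear interpolation
between order statistics (R type 7) -- stated explicitly because percentile
conventions differ.

Two variance-reduction conventions are deliberate: cohorts built from the
same seed share their random-effect draws and uniform deviates (common
random numbers), and fold-change comparisons across renal stages use such
matched cohorts so that the AUC ratios reflect the clearance covariate
rather than Monte-Carlo noise. The noise budget drove this choice: with
independent cohorts of 200 the ratio of medians carries ~6% sampling error,
comparable to the effects being measured.

## Synthetic study data

The generator emulates the two pooled clinical designs: study 1 (29
subjects, one 300 mg dose, rich sampling) and study 2 (65 subjects, total
daily doses drawn from {600, 900, 1200, 1800, 2400, 3600} mg split TID,
sparse steady-state sampling, 3--5 plasma and 2 pain samples per subject in
the final interval of a 14-day course). Covariates come from truncated
normals matching the cohort summaries (age 53 +/- 11 y, weight 81.97 +/-
17.34 kg, serum creatinine 0.92 +/- 0.41 mg/dL, eGFR 90.29 +/- 22.79
mL/min/1.73 m^2, 53:41 female:male); 12% of subjects lack recorded serum
creatinine and eGFR, while their true sampled eGFR still drives the
kinetics -- missingness hides a measurement, not the physiology. Genotypes
reproduce the cohort counts (SLC22A2 79 GG / 15 GT; SLC22A4 42/39/13)
exactly when n matches the cohort total, multinomially otherwise. eGFR is
sampled directly rather than recomputed from creatinine (the CKD-EPI
equation is out of scope).

Only aggregate facts about the designs are published: subject counts, dose
ranges, ~568 plasma and ~392 pain observations, and ~9% of plasma records
below the 0.2 ug/mL quantification limit. The sampling schedules
(0/0.5/1/2/3/4/6/8/10/12 h plasma and 0--12 h pain grids for study 1) are
therefore synthetic conventions chosen so the generated datasets land on
those totals -- including the pre-dose and early samples whose censoring
produces the reported below-limit fraction -- and are not reported facts.
What passing tests show is that the pipeline recovers a model of this
structure from data of this size and information content; they cannot
certify behavior on features the generator does not emulate (dose-dependent
bioavailability, occasion-to-occasion variability, dropout, titration,
extended-release kinetics).

## Estimation

The marginal likelihood integrates the random effects by a Laplace
approximation with exact automatic-differentiation derivatives (TMB); the
estimation method is a package design choice -- the model, not the
optimizer, is the scientific object, and parameter-recovery checks are the
acceptance surface. Plasma values below the quantification limit enter the
likelihood as interval-censored on [0, LLOQ), i.e. the Gaussian probability
mass of the prediction on that finite interval. VAS records sitting exactly
on the scale bounds (10 or 0) are treated tobit-style as the mass at or
beyond the bound: the bounded instrument pins ~10--15% of baseline scores
at the ceiling when the true score plus noise exceeds 10, and ignoring this
censors the upper tail and biases the influx rate low (we measured ~-30%
on ke1 before adopting the boundary likelihood).

Two numerical choices matter:

* The dose-onset step (concentration = 0 before lag) makes the conditional
  likelihood only piecewise smooth in tlag; the estimation kernel uses a
  sigmoidal onset switch of width 0.01 h -- far narrower than any sampling
  interval, and the tri-exponential sum vanishes at onset, so the model
  change is negligible while the objective becomes smooth enough for
  quasi-Newton optimization.
* Nested model comparisons (stepwise likelihood-ratio selection) warm-start
  each candidate fit from its parent model's optimum, so OFV differences
  are computed within one likelihood basin; cold starts of nested fits can
  land in different local basins and corrupt small OFV differences.

Development follows the staged sequence: the PK model is fitted to plasma
data alone, PD development can fix the population PK parameters, and a
final joint fit frees everything except the fixed trio (IC50, ke2, Imax).
Covariate selection is forward inclusion at a 3.84 OFV drop per degree of
freedom (p < 0.05) and backward deletion at 6.63 (p < 0.01), with missing
continuous covariates median-imputed. Initial values come from dataset
heuristics (clearance from the naive steady-state mass balance of
multiple-dose subjects; baseline score from early pain records) plus
documented generic defaults. `fit_population_model()` exposes jittered
multi-start (`n_starts`), but the default is a single start: from the
heuristic inits the Laplace fits proved stable on synthetic data, and the
nested warm-start chain already guards the comparisons that are sensitive
to basins. Convergence is declared when the optimizer reports success or
when a restart cannot improve the objective (the "false convergence"
diagnostic of `nlminb` is routine at genuine optima of piecewise-smooth
Laplace objectives). Uncertainty comes from non-parametric bootstrap
(subject resampling, 500 replicates by default, up to 20 retries per
replicate, warning below 96% convergence); covariance-based standard
errors are not provided. Visual predictive checks simulate replicate
datasets under the original design and compare observed percentiles with
the across-replicate envelope, stratified by study and channel.

## Problem sizes used by the checks

The packaged checks run at the study's own scale: cohorts of 200 for
exposure and target-attainment percentages, 100 random parameter sets for
the closed-form/ODE equivalence, and 10 replicates of the full pooled
two-study design (94 subjects) for parameter recovery. Per replicate the
recovery experiment follows the staged sequence end to end -- stepwise
selection on the plasma side, where both the true (eGFR on CL) and the
null candidate live, then PD development with the population PK fixed,
then the final joint fit. The staging matters beyond fidelity to the
modelling workflow: with an IIV SD above 2 on the effect-site influx rate
the joint likelihood is multimodal, and a collapsed mode (genotype effect
absorbed into the random effects) can capture a cold-started joint fit;
developing the PD side against fixed PK parameters first reliably lands
the final fit in the basin where the covariate structure is resolved.
Recovery fits use rel.tol 1e-4; the bias metrics they feed are assessed
at the 15% level, orders of magnitude above optimizer precision.

## Known limitations

* No dose-dependent bioavailability: intestinal LAT transport saturates at
  high doses in reality; exposures at the top doses are therefore
  upper bounds.
* No inter-occasion variability and no random-effect correlations
  (none are reported for this model).
* Homozygous TT carriers are parameterized by extrapolation
  ($e^{2\beta_g}$); no TT subject informs the coefficient.
* The Laplace approximation can bias variance components when data per
  subject are very sparse; the recovery experiments bound this for the
  reported design but not for sparser ones.
* Extended-release formulations, titration schedules and tolerability are
  out of scope.
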