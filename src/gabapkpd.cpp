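// Laplace-approximation marginal likelihood for the joint population PK/PD
// model: two-compartment oral PK (tlag, ka, CL/F, V1/F, Q, V2/F) with eGFR
// power covariate on CL, effect-compartment Imax pain model (ke1, ke2, E0,
// IC50, Imax = 1) with genotype covariate on ke1. Plasma observations carry
// additive error with left-censoring on [0, LLOQ); pain observations carry
// combined (a + b*f) error with tobit-style handling of the bounded VAS
// scale. Random effects are log-normal (logit-normal for E0) and integrated
// out by TMB's Laplace approximation.
//
// Dosing enters as "trains" of equally spaced equal doses (t0, tau, amt).
// For each observation the last two preceding doses are superposed
// explicitly -- only they can interact with the absorption lag switch --
// and all earlier doses are collapsed into the geometric-series closed form
// of the multi-dose superposition, so the cost per observation is O(trains)
// rather than O(doses).

#define TMB_LIB_INIT R_init_gabapkpd
#include <TMB.hpp>

using CppAD::CondExpGt;
using CppAD::CondExpGe;
using CppAD::CondExpLe;

// Bound a denominator away from zero, keeping its sign (both branches of a
// CondExp are always evaluated under AD, so raw division is unsafe).
template <class Type>
Type safe_denom(Type d, Type eps) {
  Type pos = CondExpGe(d, eps, d, eps);
  Type neg = CondExpLe(d, -eps, d, -eps);
  return CondExpGe(d, Type(0), pos, neg);
}

template <class Type>
Type objective_function<Type>::operator()() {
  // observations
  DATA_VECTOR(obs_time);
  DATA_IVECTOR(obs_sub);    // 0-based subject index per observation
  DATA_IVECTOR(obs_dvid);   // 1 plasma, 2 pain
  DATA_VECTOR(obs_dv);
  DATA_IVECTOR(obs_cens);   // 1 = left-censored plasma on [0, lloq);
                            // 2/3 = pain score at the upper/lower VAS bound
  DATA_VECTOR(obs_lloq);
  // dose trains and observation-train pairs
  DATA_VECTOR(train_t0);
  DATA_VECTOR(train_tau);
  DATA_VECTOR(train_amt);
  DATA_IVECTOR(pair_obs);   // observation index of each pair
  DATA_IVECTOR(pair_train); // train index of each pair
  DATA_IVECTOR(pair_m);     // number of train doses at or before the obs
  // subject-level covariates
  DATA_VECTOR(egfr);        // imputed, mL/min/1.73 m2
  DATA_VECTOR(g_oct2);      // variant-allele count, 0/1/2
  DATA_VECTOR(x_null);      // null-candidate covariate on CL
  DATA_SCALAR(egfr_ref);
  DATA_IVECTOR(eta_active); // length 7: tlag, ka, cl, v1, q, ke1, e0

  PARAMETER(log_tlag);
  PARAMETER(log_ka);
  PARAMETER(log_cl);
  PARAMETER(log_v1);
  PARAMETER(log_q);
  PARAMETER(log_v2);
  PARAMETER(log_ke1);
  PARAMETER(lgt_e0);        // logit(E0 / 10)
  PARAMETER(beta_egfr);
  PARAMETER(beta_oct2);
  PARAMETER(beta_null);
  PARAMETER(log_ic50);
  PARAMETER(log_ke2);
  PARAMETER_VECTOR(log_om); // length 7, order as eta_active
  PARAMETER(log_sig_pk);
  PARAMETER(log_sig_pd_a);
  PARAMETER(log_sig_pd_b);
  PARAMETER_MATRIX(eta);    // n_subj x 7

  int n_subj = eta.rows();
  int n_obs = obs_time.size();
  Type eps = Type(1e-9);
  Type nll = Type(0);

  // random-effect contributions
  for (int j = 0; j < 7; j++) {
    if (eta_active(j) == 0) continue;
    Type om = exp(log_om(j));
    for (int i = 0; i < n_subj; i++)
      nll -= dnorm(eta(i, j), Type(0), om, true);
  }

  Type sig_pk = exp(log_sig_pk);
  Type sig_a = exp(log_sig_pd_a);
  Type sig_b = exp(log_sig_pd_b);
  Type ic50 = exp(log_ic50);
  Type ke2 = exp(log_ke2);

  // individual parameters and disposition constants
  vector<Type> tlag(n_subj), ka(n_subj), v1(n_subj), ke1(n_subj), e0(n_subj);
  vector<Type> lam1(n_subj), lam2(n_subj), co1(n_subj), co2(n_subj), co3(n_subj);
  for (int i = 0; i < n_subj; i++) {
    tlag(i) = exp(log_tlag + eta(i, 0));
    ka(i)   = exp(log_ka + eta(i, 1));
    Type cl = exp(log_cl + beta_egfr * log(egfr(i) / egfr_ref)
                  + beta_null * x_null(i) + eta(i, 2));
    v1(i)   = exp(log_v1 + eta(i, 3));
    Type q  = exp(log_q + eta(i, 4));
    Type v2 = exp(log_v2);
    ke1(i)  = exp(log_ke1 + beta_oct2 * g_oct2(i) + eta(i, 5));
    e0(i)   = Type(10) * invlogit(lgt_e0 + eta(i, 6));
    Type k10 = cl / v1(i), k12 = q / v1(i), k21 = q / v2;
    Type s = k10 + k12 + k21;
    Type root = sqrt(s * s - Type(4) * k10 * k21);
    lam1(i) = (s + root) / Type(2);
    lam2(i) = (s - root) / Type(2);
    co1(i) = (k21 - lam1(i)) / (safe_denom(ka(i) - lam1(i), eps) * safe_denom(lam2(i) - lam1(i), eps));
    co2(i) = (k21 - lam2(i)) / (safe_denom(ka(i) - lam2(i), eps) * safe_denom(lam1(i) - lam2(i), eps));
    co3(i) = (k21 - ka(i))   / (safe_denom(lam1(i) - ka(i), eps) * safe_denom(lam2(i) - ka(i), eps));
  }

  // accumulate predictions over observation-train pairs
  vector<Type> cp(n_obs); cp.setZero();
  vector<Type> ceq(n_obs); ceq.setZero();  // Ce before the 1000*ke1 scale
  for (int p = 0; p < pair_obs.size(); p++) {
    int m = pair_m(p);
    if (m == 0) continue;
    int k = pair_obs(p);
    int tr = pair_train(p);
    int i = obs_sub(k);
    bool need_ce = (obs_dvid(k) == 2);
    Type tau = train_tau(tr);
    Type ul = obs_time(k) - (train_t0(tr) + Type(m - 1) * tau) - tlag(i);
    Type f = train_amt(tr) * ka(i) / v1(i);
    // last two doses explicitly, with the smooth onset switch (width
    // 0.01 h; the hard u > 0 step makes the conditional likelihood only
    // piecewise smooth in tlag and traps gradient optimizers at kinks).
    // u is clamped at -1 h, where the switch is already ~1e-44, so
    // pre-onset exponentials can never overflow into the AD gradient.
    int nex = m < 2 ? m : 2;
    for (int x = 0; x < nex; x++) {
      Type u = ul + Type(x) * tau;
      Type uc = CondExpGt(u, Type(-1), u, Type(-1));
      Type w = invlogit(uc / Type(0.01));
      Type e1 = exp(-lam1(i) * uc), e2 = exp(-lam2(i) * uc), e3 = exp(-ka(i) * uc);
      cp(k) += w * f * (co1(i) * e1 + co2(i) * e2 + co3(i) * e3);
      if (need_ce) {
        Type eke = exp(-ke2 * uc);
        Type g1 = (e1 - eke) / safe_denom(ke2 - lam1(i), eps);
        Type g2 = (e2 - eke) / safe_denom(ke2 - lam2(i), eps);
        Type g3 = (e3 - eke) / safe_denom(ke2 - ka(i), eps);
        ceq(k) += w * f * (co1(i) * g1 + co2(i) * g2 + co3(i) * g3);
      }
    }
    // doses 3..m before the observation: geometric-series superposition.
    // Their lags from the observation are ub + j*tau, j = 0..m-3, with
    // ub >= 2*tau - tlag > 0 for any physiological lag; all exponents are
    // negative, so the sum is numerically stable.
    if (m > 2) {
      Type ub = ul + Type(2) * tau;
      ub = CondExpGt(ub, Type(0), ub, Type(0));
      Type mm = Type(m - 2);
      Type geo1 = exp(-lam1(i) * ub) * (Type(1) - exp(-lam1(i) * mm * tau)) /
                  safe_denom(Type(1) - exp(-lam1(i) * tau), eps);
      Type geo2 = exp(-lam2(i) * ub) * (Type(1) - exp(-lam2(i) * mm * tau)) /
                  safe_denom(Type(1) - exp(-lam2(i) * tau), eps);
      Type geo3 = exp(-ka(i) * ub) * (Type(1) - exp(-ka(i) * mm * tau)) /
                  safe_denom(Type(1) - exp(-ka(i) * tau), eps);
      cp(k) += f * (co1(i) * geo1 + co2(i) * geo2 + co3(i) * geo3);
      if (need_ce) {
        Type geok = exp(-ke2 * ub) * (Type(1) - exp(-ke2 * mm * tau)) /
                    safe_denom(Type(1) - exp(-ke2 * tau), eps);
        Type g1 = (geo1 - geok) / safe_denom(ke2 - lam1(i), eps);
        Type g2 = (geo2 - geok) / safe_denom(ke2 - lam2(i), eps);
        Type g3 = (geo3 - geok) / safe_denom(ke2 - ka(i), eps);
        ceq(k) += f * (co1(i) * g1 + co2(i) * g2 + co3(i) * g3);
      }
    }
  }

  // observation likelihood
  for (int k = 0; k < n_obs; k++) {
    int i = obs_sub(k);
    if (obs_dvid(k) == 1) {
      if (obs_cens(k) == 1) {
        // interval-censored on [0, lloq)
        Type zu = (obs_lloq(k) - cp(k)) / sig_pk;
        Type zl = (Type(0) - cp(k)) / sig_pk;
        Type pr = pnorm(zu) - pnorm(zl);
        pr = CondExpGt(pr, Type(1e-12), pr, Type(1e-12));
        nll -= log(pr);
      } else {
        nll -= dnorm(obs_dv(k), cp(k), sig_pk, true);
      }
    } else {
      Type ce = Type(1000) * ke1(i) * ceq(k);  // ng/mL
      Type pain = e0(i) * (Type(1) - ce / (ic50 + ce));
      Type sd = sig_a + sig_b * pain;
      sd = CondExpGt(sd, Type(1e-6), sd, Type(1e-6));
      if (obs_cens(k) == 2) {
        // VAS pinned at the ceiling: probability mass at or above 10
        Type pr = Type(1) - pnorm((Type(10) - pain) / sd);
        pr = CondExpGt(pr, Type(1e-12), pr, Type(1e-12));
        nll -= log(pr);
      } else if (obs_cens(k) == 3) {
        // VAS pinned at the floor: mass at or below 0
        Type pr = pnorm((Type(0) - pain) / sd);
        pr = CondExpGt(pr, Type(1e-12), pr, Type(1e-12));
        nll -= log(pr);
      } else {
        nll -= dnorm(obs_dv(k), pain, sd, true);
      }
    }
  }
  return nll;
}
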