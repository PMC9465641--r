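// Closed-form linear 1/2-compartment IV-infusion kinetics and the
// Laplace-approximation marginal likelihood used by the estimation engine.
// Concentrations are central-compartment amount / V; doses are zero-order
// infusions (rate = amount / duration) superposed by linearity.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Disposition {
  int n;             // number of exponential terms (1 or 2)
  double lam[2];     // macro rate constants (alpha >= beta)
  double a[2];       // bolus coefficients, sum(a) = 1
  bool degen;        // repeated-root branch (alpha ~= beta)
  double k21;
};

// relative gap below which alpha/beta are treated as a repeated root
const double DEGEN_TOL = 1e-9;

Disposition disposition(double V, double V2, double CL, double CL2, int ncmt) {
  Disposition d;
  if (ncmt == 1) {
    d.n = 1; d.degen = false;
    d.lam[0] = CL / V; d.a[0] = 1.0;
    d.lam[1] = 0.0; d.a[1] = 0.0; d.k21 = 0.0;
    return d;
  }
  const double k10 = CL / V, k12 = CL2 / V, k21 = CL2 / V2;
  const double s = k10 + k12 + k21, p = k10 * k21;
  double disc = s * s - 4.0 * p;
  if (disc < 0.0) disc = 0.0;           // numerically degenerate
  const double root = std::sqrt(disc);
  const double alpha = 0.5 * (s + root);
  const double beta  = (alpha > 0.0) ? p / alpha : 0.0;  // stable small root
  d.k21 = k21;
  d.lam[0] = alpha; d.lam[1] = beta;
  if (alpha - beta < DEGEN_TOL * alpha) {
    d.n = 2; d.degen = true;
    d.a[0] = 1.0; d.a[1] = 0.0;
  } else {
    d.n = 2; d.degen = false;
    d.a[0] = (alpha - k21) / (alpha - beta);
    d.a[1] = (k21 - beta) / (alpha - beta);
  }
  return d;
}

// F(t) = integral_0^t of the unit-bolus concentration kernel (t >= 0)
inline double Fcum(const Disposition& d, double V, double t) {
  if (t <= 0.0) return 0.0;
  if (d.degen) {
    const double al = d.lam[0], e = std::exp(-al * t);
    return ((1.0 - e) / al -
            (al - d.k21) * (1.0 - e * (1.0 + al * t)) / (al * al)) / V;
  }
  double s = 0.0;
  for (int i = 0; i < d.n; ++i)
    s += d.a[i] * (1.0 - std::exp(-d.lam[i] * t)) / d.lam[i];
  return s / V;
}

// Phi(t) = integral_0^t of F
inline double Phicum(const Disposition& d, double V, double t) {
  if (t <= 0.0) return 0.0;
  if (d.degen) {
    const double al = d.lam[0], e = std::exp(-al * t);
    const double term1 = t / al - (1.0 - e) / (al * al);
    const double inner = t - (2.0 - e * (2.0 + al * t)) / al;
    return (term1 - (al - d.k21) * inner / (al * al)) / V;
  }
  double s = 0.0;
  for (int i = 0; i < d.n; ++i)
    s += (d.a[i] / d.lam[i]) *
         (t - (1.0 - std::exp(-d.lam[i] * t)) / d.lam[i]);
  return s / V;
}

// concentration at absolute time t from one infusion (start t0, duration T,
// amount amt); rate = amt / T
inline double conc_dose(const Disposition& d, double V, double t,
                        double t0, double T, double amt) {
  const double u = t - t0;
  if (u <= 0.0) return 0.0;
  const double R = amt / T;
  return R * (Fcum(d, V, u) - Fcum(d, V, u - T));
}

inline double auc_dose(const Disposition& d, double V, double t0abs,
                       double T, double amt, double lo, double hi) {
  // integral over absolute [lo, hi] of conc_dose
  const double u1 = std::max(lo - t0abs, 0.0), u2 = std::max(hi - t0abs, 0.0);
  if (u2 <= u1) return 0.0;
  const double R = amt / T;
  const double main_ = Phicum(d, V, u2) - Phicum(d, V, u1);
  const double tail = Phicum(d, V, std::max(u2 - T, 0.0)) -
                      Phicum(d, V, std::max(u1 - T, 0.0));
  return R * (main_ - tail);
}

struct SubjData {
  const double* ot; const double* dv; int nobs;
  const double* dt0; const double* ddur; const double* damt; int ndose;
};

// -2 log joint density of (y, eta) for one subject
double g_joint(const SubjData& sd, const double* base, int ncmt,
               const int* iiv_idx, int d, const arma::vec& eta,
               const double* omega2, int res_code,
               double sig_add, double sig_prop) {
  double pv[4] = { base[0], base[1], base[2], base[3] }; // V V2 CL CL2
  for (int k = 0; k < d; ++k) pv[iiv_idx[k]] *= std::exp(eta[k]);
  Disposition disp = disposition(pv[0], pv[1], pv[2], pv[3], ncmt);
  const double LOG2PI = 1.8378770664093454836;
  double g = 0.0;
  for (int j = 0; j < sd.nobs; ++j) {
    double f = 0.0;
    for (int m = 0; m < sd.ndose; ++m)
      f += conc_dose(disp, pv[0], sd.ot[j], sd.dt0[m], sd.ddur[m], sd.damt[m]);
    double v = 0.0;
    if (res_code == 0) v = sig_add * sig_add;
    else if (res_code == 1) v = sig_prop * f * sig_prop * f;
    else v = sig_add * sig_add + sig_prop * f * sig_prop * f;
    if (v < 1e-12) v = 1e-12;
    const double r = sd.dv[j] - f;
    g += LOG2PI + std::log(v) + r * r / v;
  }
  for (int k = 0; k < d; ++k)
    g += LOG2PI + std::log(omega2[k]) + eta[k] * eta[k] / omega2[k];
  return g;
}

// damped Newton minimization of g over eta with finite differences;
// returns minimized g, mode in eta, Hessian in H
double inner_min(const SubjData& sd, const double* base, int ncmt,
                 const int* iiv_idx, int d, const double* omega2,
                 int res_code, double sig_add, double sig_prop,
                 arma::vec& eta, arma::mat& H) {
  const double h = 1e-4;
  auto gf = [&](const arma::vec& e) {
    return g_joint(sd, base, ncmt, iiv_idx, d, e, omega2,
                   res_code, sig_add, sig_prop);
  };
  double g0 = gf(eta);
  for (int iter = 0; iter < 60; ++iter) {
    arma::vec grad(d);
    arma::mat Hm(d, d);
    std::vector<double> gp(d), gm(d);
    for (int i = 0; i < d; ++i) {
      arma::vec e = eta; e[i] += h; gp[i] = gf(e);
      e[i] -= 2 * h; gm[i] = gf(e);
      grad[i] = (gp[i] - gm[i]) / (2 * h);
      Hm(i, i) = (gp[i] - 2 * g0 + gm[i]) / (h * h);
    }
    for (int i = 0; i < d; ++i)
      for (int j = i + 1; j < d; ++j) {
        arma::vec e = eta; e[i] += h; e[j] += h; double fpp = gf(e);
        e[j] -= 2 * h; double fpm = gf(e);
        e[i] -= 2 * h; double fmm = gf(e);
        e[j] += 2 * h; double fmp = gf(e);
        Hm(i, j) = Hm(j, i) = (fpp - fpm - fmp + fmm) / (4 * h * h);
      }
    double gnorm = arma::norm(grad, 2);
    if (gnorm < 1e-8) break;
    // Levenberg damping: ensure positive definite step
    double lambda = 0.0;
    arma::vec step;
    for (int tries = 0; tries < 8; ++tries) {
      arma::mat Hd = Hm + lambda * arma::eye(d, d);
      bool ok = arma::solve(step, Hd, grad, arma::solve_opts::no_approx);
      if (ok && arma::dot(step, grad) > 0.0) break;
      lambda = (lambda == 0.0) ? 1.0 : lambda * 10.0;
    }
    double sn = arma::norm(step, 2);
    if (sn > 2.0) step *= 2.0 / sn;          // trust region
    double t = 1.0, gnew = 0.0;
    bool moved = false;
    for (int ls = 0; ls < 12; ++ls) {
      arma::vec cand = eta - t * step;
      gnew = gf(cand);
      if (gnew <= g0) { eta = cand; moved = true; break; }
      t *= 0.5;
    }
    if (!moved) break;
    bool conv = (g0 - gnew < 1e-10);
    g0 = gnew;
    if (conv) break;
  }
  // final Hessian at the mode, Richardson-extrapolated (the log-determinant
  // enters the marginal likelihood, so plain O(h^2) differences leave a
  // visible bias)
  auto hess_at = [&](double hh) {
    arma::mat Hm(d, d);
    for (int i = 0; i < d; ++i) {
      arma::vec e = eta; e[i] += hh; double fp = gf(e);
      e[i] -= 2 * hh; double fm = gf(e);
      Hm(i, i) = (fp - 2 * g0 + fm) / (hh * hh);
    }
    for (int i = 0; i < d; ++i)
      for (int j = i + 1; j < d; ++j) {
        arma::vec e = eta; e[i] += hh; e[j] += hh; double fpp = gf(e);
        e[j] -= 2 * hh; double fpm = gf(e);
        e[i] -= 2 * hh; double fmm = gf(e);
        e[j] += 2 * hh; double fmp = gf(e);
        Hm(i, j) = Hm(j, i) = (fpp - fpm - fmp + fmm) / (4 * hh * hh);
      }
    return Hm;
  };
  H = (4.0 * hess_at(5e-4) - hess_at(1e-3)) / 3.0;
  return g0;
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_conc(NumericVector times, NumericVector dose_t0,
                       NumericVector dose_dur, NumericVector dose_amt,
                       double V, double V2, double CL, double CL2,
                       int ncmt) {
  Disposition d = disposition(V, V2, CL, CL2, ncmt);
  const int n = times.size(), m = dose_t0.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double c = 0.0;
    for (int j = 0; j < m; ++j)
      c += conc_dose(d, V, times[i], dose_t0[j], dose_dur[j], dose_amt[j]);
    out[i] = c;
  }
  return out;
}

// [[Rcpp::export]]
double cpp_auc(double t0, double t1, NumericVector dose_t0,
               NumericVector dose_dur, NumericVector dose_amt,
               double V, double V2, double CL, double CL2, int ncmt) {
  Disposition d = disposition(V, V2, CL, CL2, ncmt);
  double a = 0.0;
  for (int j = 0; j < dose_t0.size(); ++j)
    a += auc_dose(d, V, dose_t0[j], dose_dur[j], dose_amt[j], t0, t1);
  return a;
}

// Laplace-approximate -2 log marginal likelihood, summed over subjects.
// base: n_subj x 4 matrix of individual structural parameters before IIV
// (V, V2, CL, CL2); iiv_idx: 0-based indices into that row that carry a
// log-normal random effect with variances omega2.
// [[Rcpp::export]]
List cpp_nll(NumericMatrix base, int ncmt, IntegerVector iiv_idx,
             NumericVector omega2, int res_code, double sig_add,
             double sig_prop, NumericVector obs_time, NumericVector obs_dv,
             IntegerVector obs_off, NumericVector dose_t0,
             NumericVector dose_dur, NumericVector dose_amt,
             IntegerVector dose_off, bool return_eta,
             Nullable<NumericMatrix> eta_init = R_NilValue) {
  const int ns = base.nrow();
  const double LOG2PI = 1.8378770664093454836;
  // drop effectively-zero variances (treated as no random effect)
  std::vector<int> idx; std::vector<double> om;
  for (int k = 0; k < iiv_idx.size(); ++k)
    if (omega2[k] > 1e-12) { idx.push_back(iiv_idx[k]); om.push_back(omega2[k]); }
  const int d = (int)idx.size();
  NumericMatrix eta_out(ns, std::max(d, 1));
  bool have_init = eta_init.isNotNull();
  NumericMatrix einit;
  if (have_init) {
    einit = NumericMatrix(eta_init);
    if (einit.nrow() != ns || einit.ncol() < d) have_init = false;
  }
  double total = 0.0;
  bool ok = true;
  for (int i = 0; i < ns; ++i) {
    SubjData sd;
    sd.ot = &obs_time[0] + obs_off[i];
    sd.dv = &obs_dv[0] + obs_off[i];
    sd.nobs = obs_off[i + 1] - obs_off[i];
    sd.dt0 = &dose_t0[0] + dose_off[i];
    sd.ddur = &dose_dur[0] + dose_off[i];
    sd.damt = &dose_amt[0] + dose_off[i];
    sd.ndose = dose_off[i + 1] - dose_off[i];
    double b[4] = { base(i, 0), base(i, 1), base(i, 2), base(i, 3) };
    if (sd.nobs == 0) continue;
    if (d == 0) {
      arma::vec e0(1, arma::fill::zeros);
      total += g_joint(sd, b, ncmt, nullptr, 0, e0, nullptr,
                       res_code, sig_add, sig_prop);
      continue;
    }
    arma::vec eta(d, arma::fill::zeros);
    if (have_init)
      for (int k = 0; k < d; ++k) eta[k] = einit(i, k);
    arma::mat H(d, d);
    double gmin = inner_min(sd, b, ncmt, idx.data(), d, om.data(),
                            res_code, sig_add, sig_prop, eta, H);
    double ldet, sign;
    arma::log_det(ldet, sign, H);
    if (sign <= 0.0 || !std::isfinite(ldet)) { ok = false; ldet = 0.0; }
    total += gmin + ldet - d * (LOG2PI + std::log(2.0));
    for (int k = 0; k < d; ++k) eta_out(i, k) = eta[k];
  }
  return List::create(_["nll"] = total, _["eta"] = eta_out, _["ok"] = ok,
                      _["d"] = d);
}
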