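// Wiener first-passage-time machinery and the hierarchical sampler.
//
// Conventions (documented in the package vignette):
//  * diffusion coefficient fixed at 1;
//  * w is the starting fraction measured from the LOWER boundary;
//  * nf_density() is the drift-free series part of the density of absorption
//    at the lower boundary, in normalized time tau = t / a^2;
//  * the full lower-boundary density is
//      f_lower(t | v, a, w) = nf_density(t/a^2, w) / a^2 * exp(-v*a*w - v^2 t/2)
//    and the upper boundary follows by reflection (v -> -v, w -> 1-w);
//  * drift-rate variability sv is marginalized in closed form (Gaussian
//    integral over the drift exponent), non-decision-time variability st by
//    fixed-order Gauss-Legendre quadrature over t0' in [t0-st/2, t0+st/2].

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// Drift-free series part of the lower-boundary FPT density in normalized
// time tau, start fraction w.  Switches between the small-time and
// large-time representations by whichever needs fewer terms for truncation
// error <= eps (Navarro-Fuss style term-count bounds).
static double nf_density(double tau, double w, double eps) {
  if (tau <= 0.0) return 0.0;

  double ks;
  if (2.0 * std::sqrt(2.0 * M_PI * tau) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tau * std::log(2.0 * eps * std::sqrt(2.0 * M_PI * tau)));
    double lb = std::sqrt(tau) + 1.0;
    if (ks < lb) ks = lb;
  } else {
    ks = 2.0;
  }

  double kl;
  if (M_PI * tau * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tau * eps) / (M_PI * M_PI * tau));
    double lb = 1.0 / (M_PI * std::sqrt(tau));
    if (kl < lb) kl = lb;
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tau));
  }

  double f;
  if (ks < kl) {
    int K = (int)std::ceil(ks);
    int lo = -(int)std::floor((K - 1) / 2.0);
    int hi = (int)std::ceil((K - 1) / 2.0);
    double s = 0.0;
    for (int k = lo; k <= hi; ++k) {
      double u = w + 2.0 * k;
      s += u * std::exp(-u * u / (2.0 * tau));
    }
    f = s / std::sqrt(2.0 * M_PI * tau * tau * tau);
  } else {
    int K = (int)std::ceil(kl);
    double s = 0.0;
    for (int k = 1; k <= K; ++k) {
      s += k * std::exp(-k * k * M_PI * M_PI * tau / 2.0) *
           std::sin(k * M_PI * w);
    }
    f = s * M_PI;
  }
  return f > 0.0 ? f : 0.0;
}

// Full defective density at the lower boundary, sv marginalized when sv > 0.
static double wfpt_lower(double t, double v, double a, double w, double sv,
                         double eps) {
  if (t <= 0.0) return 0.0;
  double g = nf_density(t / (a * a), w, eps) / (a * a);
  if (g <= 0.0) return 0.0;
  double m;
  if (sv > 0.0) {
    double s2 = 1.0 + sv * sv * t;
    m = std::exp((a * a * w * w * sv * sv - 2.0 * a * w * v - v * v * t) /
                 (2.0 * s2)) /
        std::sqrt(s2);
  } else {
    m = std::exp(-v * a * w - v * v * t / 2.0);
  }
  return g * m;
}

static inline double density_boundary(double t, int upper, double v, double a,
                                      double z, double sv, double eps) {
  return upper ? wfpt_lower(t, -v, a, 1.0 - z, sv, eps)
               : wfpt_lower(t, v, a, z, sv, eps);
}

// Single-trial density at response time rt: st-marginalized by
// Gauss-Legendre nodes (glx, glw on [-1, 1]); uniform average over
// t0' in [t0 - st/2, t0 + st/2] equals 0.5 * sum_j glw_j f(rt - t0'_j).
static double trial_density(double rt, int upper, double v, double a, double z,
                            double t0, double sv, double st, double eps,
                            const double* glx, const double* glw, int ngl) {
  if (st > 0.0) {
    double h = st / 2.0, acc = 0.0;
    for (int j = 0; j < ngl; ++j) {
      double td = rt - (t0 + h * glx[j]);
      if (td > 0.0) acc += glw[j] * density_boundary(td, upper, v, a, z, sv, eps);
    }
    return 0.5 * acc;
  }
  return density_boundary(rt - t0, upper, v, a, z, sv, eps);
}

// [[Rcpp::export]]
NumericVector cpp_wfpt_density(NumericVector t, int upper, double v, double a,
                               double z, double sv, double eps) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = density_boundary(t[i], upper, v, a, z, sv, eps);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_trial_loglik(NumericVector rt, IntegerVector upper,
                               NumericVector v, NumericVector a,
                               NumericVector z, NumericVector t0, double sv,
                               double st, double eps, NumericVector glx,
                               NumericVector glw) {
  int n = rt.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double d = trial_density(rt[i], upper[i], v[i], a[i], z[i], t0[i], sv, st,
                             eps, glx.begin(), glw.begin(), glx.size());
    out[i] = d > 0.0 ? std::log(d) : NEG_INF;
  }
  return out;
}

// Euler-Maruyama forward simulation; one v' ~ N(v, sv) and one
// t0' ~ U(t0 - st/2, t0 + st/2) per trial; censored when rt would exceed
// the deadline.  Uses R's RNG stream.
// [[Rcpp::export]]
List cpp_simulate_trials(NumericVector v, NumericVector a, NumericVector z,
                         NumericVector t0, double sv, double st, double dt,
                         double deadline) {
  int n = v.size();
  NumericVector rt(n);
  IntegerVector boundary(n), censored(n);
  double sdt = std::sqrt(dt);
  for (int i = 0; i < n; ++i) {
    double vp = sv > 0.0 ? v[i] + sv * norm_rand() : v[i];
    double t0p = st > 0.0 ? t0[i] + st * (unif_rand() - 0.5) : t0[i];
    double x = z[i] * a[i];
    double tt = 0.0;
    int hit = -1;
    while (tt + t0p <= deadline) {
      x += vp * dt + sdt * norm_rand();
      tt += dt;
      if (x >= a[i]) { hit = 1; break; }
      if (x <= 0.0) { hit = 0; break; }
    }
    if (hit < 0 || tt + t0p > deadline) {
      rt[i] = NA_REAL;
      boundary[i] = NA_INTEGER;
      censored[i] = 1;
    } else {
      rt[i] = tt + t0p;
      boundary[i] = hit;
      censored[i] = 0;
    }
  }
  return List::create(_["rt"] = rt, _["boundary"] = boundary,
                      _["censored"] = censored);
}

// ---------------------------------------------------------------------------
// Hierarchical sampler
// ---------------------------------------------------------------------------
//
// Parameter vector layout (kind: 0 = null, 1 = fc, 2 = full):
//   0 mu_v, 1 sigma_v, 2 mu_a, 3 sigma_a, 4 mu_t0, 5 sigma_t0, 6 sv, 7 st
//   [kind >= 1] 8 mu_bF, 9 sigma_bF, 10 mu_bC, 11 sigma_bC
//   [kind == 2] +0 beta_v, +1 beta_a, +2 beta_t
//   subjects: v_i, a_i, t0_i [, bF_i, bC_i] blocks of length nsub.
//
// z is fixed at 0.5 so the drift-free series part is identical for both
// boundaries; it is cached per (trial, quadrature node) and only recomputed
// for proposals that move a_eff, t0_eff or st.

struct Priors {
  double mu_v_m, mu_v_s;      // Normal
  double mu_a_shape, mu_a_scale;  // Gamma
  double mu_t0_m, mu_t0_s;    // Normal truncated at 0
  double eff_s;               // effect / slope means: Normal(0, eff_s)
  double sigma_s;             // group SDs: Half-Normal(sigma_s)
  double sv_s, st_s;          // Half-Normal scales
};

class Sampler {
 public:
  int kind, nsub, ntr, ngl, np, base;
  std::vector<int> up;
  std::vector<double> rt, F, C;
  std::vector<double> score;
  std::vector<int> ts, te;  // per-subject [start, end) trial ranges
  Priors P;
  double eps;
  std::vector<double> glx, glw;

  std::vector<double> th, L, G, T;
  double sumL;
  std::vector<double> Gtmp, Ttmp, Ltmp;
  std::vector<double> step;
  std::vector<int> acc, tries;

  int i_v(int i) const { return base + i; }
  int i_a(int i) const { return base + nsub + i; }
  int i_t0(int i) const { return base + 2 * nsub + i; }
  int i_bF(int i) const { return base + 3 * nsub + i; }
  int i_bC(int i) const { return base + 4 * nsub + i; }
  int i_mu_bF() const { return 8; }
  int i_sigma_bF() const { return 9; }
  int i_mu_bC() const { return 10; }
  int i_sigma_bC() const { return 11; }
  int i_beta_v() const { return 12; }
  int i_beta_a() const { return 13; }
  int i_beta_t() const { return 14; }

  double beta_v() const { return kind == 2 ? th[i_beta_v()] : 0.0; }
  double beta_a() const { return kind == 2 ? th[i_beta_a()] : 0.0; }
  double beta_t() const { return kind == 2 ? th[i_beta_t()] : 0.0; }

  static double dnorm_log(double x, double m, double s) {
    if (s <= 0.0) return NEG_INF;
    double zsc = (x - m) / s;
    return -0.5 * zsc * zsc - std::log(s);
  }
  static double halfnorm_log(double x, double s) {
    if (x < 0.0) return NEG_INF;
    return -x * x / (2.0 * s * s);
  }

  // Hyperprior log-density of one group-level node at a given value.
  double hyper_lp(int node, double x) const {
    if (node == 0) return dnorm_log(x, P.mu_v_m, P.mu_v_s);
    if (node == 2) {
      if (x <= 0.0) return NEG_INF;
      return (P.mu_a_shape - 1.0) * std::log(x) - x / P.mu_a_scale;
    }
    if (node == 4) {
      if (x < 0.0) return NEG_INF;
      return dnorm_log(x, P.mu_t0_m, P.mu_t0_s);
    }
    if (node == 6) return halfnorm_log(x, P.sv_s);
    if (node == 7) return halfnorm_log(x, P.st_s);
    if (node == 1 || node == 3 || node == 5) return halfnorm_log(x, P.sigma_s);
    if (kind >= 1 && (node == i_sigma_bF() || node == i_sigma_bC()))
      return halfnorm_log(x, P.sigma_s);
    // effect means and covariate slopes
    return dnorm_log(x, 0.0, P.eff_s);
  }

  // All subject-level prior terms for subject i under state v (group nodes).
  double subj_prior_lp(const std::vector<double>& t, int i) const {
    double ai = t[i_a(i)];
    if (ai <= 0.0) return NEG_INF;
    double lp = dnorm_log(t[i_v(i)], t[0], t[1]);
    lp += dnorm_log(ai, t[2], t[3]);
    lp += dnorm_log(t[i_t0(i)], t[4], t[5]);
    if (kind >= 1) {
      lp += dnorm_log(t[i_bF(i)], t[i_mu_bF()], t[i_sigma_bF()]);
      lp += dnorm_log(t[i_bC(i)], t[i_mu_bC()], t[i_sigma_bC()]);
    }
    return lp;
  }

  // Fill series cache rows for subject i given effective a, t0 and st.
  // Returns false on support violation.
  bool fill_G(int i, double aeff, double t0eff, double st, double* Gout,
              double* Tout) const {
    if (aeff <= 0.0) return false;
    if (t0eff - st / 2.0 < 0.0) return false;
    double a2 = aeff * aeff;
    double h = st / 2.0;
    int nn = st > 0.0 ? ngl : 1;
    for (int t = ts[i]; t < te[i]; ++t) {
      for (int j = 0; j < nn; ++j) {
        double td = st > 0.0 ? rt[t] - (t0eff + h * glx[j]) : rt[t] - t0eff;
        int off = t * ngl + j;
        Tout[off] = td;
        Gout[off] = td > 0.0 ? nf_density(td / a2, 0.5, eps) / a2 : 0.0;
      }
    }
    return true;
  }

  // Trial log-likelihood for subject i from a series cache, given the
  // drift-side parameters.  w = 0.5 throughout.
  double calc_L(int i, const double* Gm, const double* Tm, double vi,
                double bFi, double bCi, double bv, double aeff, double sv,
                double st) const {
    double sc = score[i];
    double sv2 = sv * sv;
    double aq = 0.25 * aeff * aeff * sv2;
    int nn = st > 0.0 ? ngl : 1;
    double w0 = st > 0.0 ? 1.0 : 2.0;  // st = 0: single node, weight 2
    double ll = 0.0;
    for (int t = ts[i]; t < te[i]; ++t) {
      double veff = vi + bFi * F[t] + bCi * C[t] + bv * sc;
      double vs = up[t] ? -veff : veff;
      double sum = 0.0;
      for (int j = 0; j < nn; ++j) {
        int off = t * ngl + j;
        double g = Gm[off];
        if (g <= 0.0) continue;
        double td = Tm[off];
        double m;
        if (sv > 0.0) {
          double s2 = 1.0 + sv2 * td;
          m = std::exp((aq - aeff * vs - vs * vs * td) / (2.0 * s2)) /
              std::sqrt(s2);
        } else {
          m = std::exp(-0.5 * aeff * vs - 0.5 * vs * vs * td);
        }
        sum += (st > 0.0 ? glw[j] : w0) * g * m;
      }
      double dens = 0.5 * sum;
      if (dens <= 0.0) return NEG_INF;
      ll += std::log(dens);
    }
    return ll;
  }

  double subj_L_current(int i) {
    return calc_L(i, G.data(), T.data(), th[i_v(i)],
                  kind >= 1 ? th[i_bF(i)] : 0.0,
                  kind >= 1 ? th[i_bC(i)] : 0.0, beta_v(),
                  th[i_a(i)] + beta_a() * score[i], th[6], th[7]);
  }

  // Full initialization of caches; returns false if log posterior is -Inf.
  bool init_state() {
    G.assign((size_t)ntr * ngl, 0.0);
    T.assign((size_t)ntr * ngl, 0.0);
    L.assign(nsub, 0.0);
    for (int i = 0; i < nsub; ++i) {
      double aeff = th[i_a(i)] + beta_a() * score[i];
      double t0eff = th[i_t0(i)] + beta_t() * score[i];
      if (!fill_G(i, aeff, t0eff, th[7], G.data(), T.data())) return false;
      L[i] = subj_L_current(i);
      if (!std::isfinite(L[i])) return false;
      if (!std::isfinite(subj_prior_lp(th, i))) return false;
    }
    sumL = 0.0;
    for (int i = 0; i < nsub; ++i) sumL += L[i];
    for (int g = 0; g < base; ++g)
      if (!std::isfinite(hyper_lp(g, th[g]))) return false;
    return true;
  }

  void bump(int node, bool accepted) {
    tries[node] += 1;
    if (accepted) acc[node] += 1;
  }

  // Group node whose full conditional involves only prior terms.
  void update_prior_node(int g) {
    double cur = th[g];
    double prop = cur + step[g] * norm_rand();
    double lp0 = hyper_lp(g, cur), lp1 = hyper_lp(g, prop);
    if (std::isfinite(lp1)) {
      th[g] = prop;
      for (int i = 0; i < nsub && std::isfinite(lp1); ++i)
        lp1 += subj_prior_lp(th, i);
      th[g] = cur;
      for (int i = 0; i < nsub; ++i) lp0 += subj_prior_lp(th, i);
      if (std::isfinite(lp1) && std::log(unif_rand()) < lp1 - lp0) {
        th[g] = prop;
        bump(g, true);
        return;
      }
    }
    bump(g, false);
  }

  // sv or beta_v: full-data likelihood, series cache unchanged.
  void update_drift_side_global(int g) {
    double cur = th[g];
    double prop = cur + step[g] * norm_rand();
    double hp1 = hyper_lp(g, prop);
    if (std::isfinite(hp1)) {
      double sv1 = g == 6 ? prop : th[6];
      double bv1 = (kind == 2 && g == i_beta_v()) ? prop : beta_v();
      double s1 = 0.0;
      bool ok = true;
      for (int i = 0; i < nsub; ++i) {
        Ltmp[i] = calc_L(i, G.data(), T.data(), th[i_v(i)],
                         kind >= 1 ? th[i_bF(i)] : 0.0,
                         kind >= 1 ? th[i_bC(i)] : 0.0, bv1,
                         th[i_a(i)] + beta_a() * score[i], sv1, th[7]);
        if (!std::isfinite(Ltmp[i])) { ok = false; break; }
        s1 += Ltmp[i];
      }
      if (ok &&
          std::log(unif_rand()) < (hp1 + s1) - (hyper_lp(g, cur) + sumL)) {
        th[g] = prop;
        L = Ltmp;
        sumL = s1;
        bump(g, true);
        return;
      }
    }
    bump(g, false);
  }

  // st, beta_a or beta_t: series cache must be rebuilt for all subjects.
  void update_geometry_global(int g) {
    double cur = th[g];
    double prop = cur + step[g] * norm_rand();
    double hp1 = hyper_lp(g, prop);
    if (std::isfinite(hp1)) {
      double st1 = g == 7 ? prop : th[7];
      double ba1 = (kind == 2 && g == i_beta_a()) ? prop : beta_a();
      double bt1 = (kind == 2 && g == i_beta_t()) ? prop : beta_t();
      double s1 = 0.0;
      bool ok = true;
      for (int i = 0; i < nsub; ++i) {
        double aeff = th[i_a(i)] + ba1 * score[i];
        double t0eff = th[i_t0(i)] + bt1 * score[i];
        if (!fill_G(i, aeff, t0eff, st1, Gtmp.data(), Ttmp.data())) {
          ok = false;
          break;
        }
        Ltmp[i] = calc_L(i, Gtmp.data(), Ttmp.data(), th[i_v(i)],
                         kind >= 1 ? th[i_bF(i)] : 0.0,
                         kind >= 1 ? th[i_bC(i)] : 0.0, beta_v(), aeff, th[6],
                         st1);
        if (!std::isfinite(Ltmp[i])) { ok = false; break; }
        s1 += Ltmp[i];
      }
      if (ok &&
          std::log(unif_rand()) < (hp1 + s1) - (hyper_lp(g, cur) + sumL)) {
        th[g] = prop;
        std::swap(G, Gtmp);
        std::swap(T, Ttmp);
        L = Ltmp;
        sumL = s1;
        bump(g, true);
        return;
      }
    }
    bump(g, false);
  }

  // Subject drift-side node: v_i, bF_i or bC_i.
  void update_subj_drift(int i, int node) {
    double cur = th[node];
    double prop = cur + step[node] * norm_rand();
    double m, s;
    if (node == i_v(i)) { m = th[0]; s = th[1]; }
    else if (node == i_bF(i)) { m = th[i_mu_bF()]; s = th[i_sigma_bF()]; }
    else { m = th[i_mu_bC()]; s = th[i_sigma_bC()]; }
    double vi = node == i_v(i) ? prop : th[i_v(i)];
    double bFi = kind >= 1 ? (node == i_bF(i) ? prop : th[i_bF(i)]) : 0.0;
    double bCi = kind >= 1 ? (node == i_bC(i) ? prop : th[i_bC(i)]) : 0.0;
    double L1 = calc_L(i, G.data(), T.data(), vi, bFi, bCi, beta_v(),
                       th[i_a(i)] + beta_a() * score[i], th[6], th[7]);
    if (std::isfinite(L1)) {
      double d = (dnorm_log(prop, m, s) + L1) - (dnorm_log(cur, m, s) + L[i]);
      if (std::log(unif_rand()) < d) {
        th[node] = prop;
        sumL += L1 - L[i];
        L[i] = L1;
        bump(node, true);
        return;
      }
    }
    bump(node, false);
  }

  // Subject geometry node: a_i or t0_i (series rows for subject i rebuilt).
  void update_subj_geometry(int i, int node) {
    double cur = th[node];
    double prop = cur + step[node] * norm_rand();
    bool is_a = node == i_a(i);
    double ai = is_a ? prop : th[i_a(i)];
    double t0i = is_a ? th[i_t0(i)] : prop;
    double m = is_a ? th[2] : th[4];
    double s = is_a ? th[3] : th[5];
    double pr1 = (is_a && prop <= 0.0) ? NEG_INF : dnorm_log(prop, m, s);
    if (std::isfinite(pr1)) {
      double aeff = ai + beta_a() * score[i];
      double t0eff = t0i + beta_t() * score[i];
      if (fill_G(i, aeff, t0eff, th[7], Gtmp.data(), Ttmp.data())) {
        double L1 = calc_L(i, Gtmp.data(), Ttmp.data(), th[i_v(i)],
                           kind >= 1 ? th[i_bF(i)] : 0.0,
                           kind >= 1 ? th[i_bC(i)] : 0.0, beta_v(), aeff,
                           th[6], th[7]);
        if (std::isfinite(L1)) {
          double d = (pr1 + L1) - (dnorm_log(cur, m, s) + L[i]);
          if (std::log(unif_rand()) < d) {
            th[node] = prop;
            int nn = th[7] > 0.0 ? ngl : 1;
            for (int t = ts[i]; t < te[i]; ++t)
              for (int j = 0; j < nn; ++j) {
                G[t * ngl + j] = Gtmp[t * ngl + j];
                T[t * ngl + j] = Ttmp[t * ngl + j];
              }
            sumL += L1 - L[i];
            L[i] = L1;
            bump(node, true);
            return;
          }
        }
      }
    }
    bump(node, false);
  }

  void sweep() {
    for (int g = 0; g < 6; ++g) update_prior_node(g);
    update_drift_side_global(6);   // sv
    update_geometry_global(7);     // st
    if (kind >= 1)
      for (int g = 8; g < 12; ++g) update_prior_node(g);
    if (kind == 2) {
      update_drift_side_global(i_beta_v());
      update_geometry_global(i_beta_a());
      update_geometry_global(i_beta_t());
    }
    for (int i = 0; i < nsub; ++i) {
      update_subj_drift(i, i_v(i));
      update_subj_geometry(i, i_a(i));
      update_subj_geometry(i, i_t0(i));
      if (kind >= 1) {
        update_subj_drift(i, i_bF(i));
        update_subj_drift(i, i_bC(i));
      }
    }
  }

  void adapt() {
    for (int g = 0; g < np; ++g) {
      if (tries[g] == 0) continue;
      double rate = (double)acc[g] / tries[g];
      if (rate > 0.5) step[g] *= 1.2;
      else if (rate < 0.3) step[g] *= 0.8;
      acc[g] = 0;
      tries[g] = 0;
    }
  }
};

static Sampler make_sampler(int kind, int nsub, IntegerVector sub,
                            NumericVector rt, IntegerVector up,
                            NumericVector F, NumericVector C,
                            NumericVector score, List prior, double eps,
                            NumericVector glx, NumericVector glw) {
  Sampler S;
  S.kind = kind;
  S.nsub = nsub;
  S.ntr = rt.size();
  S.ngl = glx.size();
  S.base = 8 + (kind >= 1 ? 4 : 0) + (kind == 2 ? 3 : 0);
  S.np = S.base + nsub * (3 + (kind >= 1 ? 2 : 0));
  S.rt.assign(rt.begin(), rt.end());
  S.up.assign(up.begin(), up.end());
  S.F.assign(F.begin(), F.end());
  S.C.assign(C.begin(), C.end());
  S.score.assign(score.begin(), score.end());
  S.glx.assign(glx.begin(), glx.end());
  S.glw.assign(glw.begin(), glw.end());
  S.eps = eps;
  // trials must arrive sorted by subject
  S.ts.assign(nsub, -1);
  S.te.assign(nsub, -1);
  for (int t = 0; t < S.ntr; ++t) {
    int i = sub[t];
    if (S.ts[i] < 0) S.ts[i] = t;
    S.te[i] = t + 1;
  }
  for (int i = 0; i < nsub; ++i)
    if (S.ts[i] < 0) stop("subject with no trials");
  S.P.mu_v_m = prior["mu_v_mean"];
  S.P.mu_v_s = prior["mu_v_sd"];
  S.P.mu_a_shape = prior["mu_a_shape"];
  S.P.mu_a_scale = prior["mu_a_scale"];
  S.P.mu_t0_m = prior["mu_t0_mean"];
  S.P.mu_t0_s = prior["mu_t0_sd"];
  S.P.eff_s = prior["effect_sd"];
  S.P.sigma_s = prior["group_sd_scale"];
  S.P.sv_s = prior["sv_scale"];
  S.P.st_s = prior["st_scale"];
  S.Gtmp.assign((size_t)S.ntr * S.ngl, 0.0);
  S.Ttmp.assign((size_t)S.ntr * S.ngl, 0.0);
  S.Ltmp.assign(nsub, 0.0);
  return S;
}

// [[Rcpp::export]]
List cpp_run_mcmc(int kind, int nsub, IntegerVector sub, NumericVector rt,
                  IntegerVector up, NumericVector F, NumericVector C,
                  NumericVector score, List prior, double eps,
                  NumericVector glx, NumericVector glw, NumericVector init,
                  NumericVector step_init, int n_samples, int n_burn) {
  Sampler S = make_sampler(kind, nsub, sub, rt, up, F, C, score, prior, eps,
                           glx, glw);
  if ((int)init.size() != S.np) stop("init length != number of parameters");
  S.th.assign(init.begin(), init.end());
  S.step.assign(step_init.begin(), step_init.end());
  S.acc.assign(S.np, 0);
  S.tries.assign(S.np, 0);
  if (!S.init_state())
    return List::create(_["ok"] = false);

  int n_keep = n_samples - n_burn;
  NumericMatrix draws(n_keep, S.np);
  NumericVector deviance(n_keep);
  for (int it = 0; it < n_samples; ++it) {
    S.sweep();
    if (it < n_burn && (it + 1) % 50 == 0) S.adapt();
    if (it == n_burn - 1)
      for (int g = 0; g < S.np; ++g) { S.acc[g] = 0; S.tries[g] = 0; }
    if (it >= n_burn) {
      int r = it - n_burn;
      for (int g = 0; g < S.np; ++g) draws(r, g) = S.th[g];
      deviance[r] = -2.0 * S.sumL;
    }
    if ((it + 1) % 200 == 0) Rcpp::checkUserInterrupt();
  }
  NumericVector rate(S.np);
  for (int g = 0; g < S.np; ++g)
    rate[g] = S.tries[g] > 0 ? (double)S.acc[g] / S.tries[g] : NA_REAL;
  return List::create(_["ok"] = true, _["draws"] = draws,
                      _["deviance"] = deviance, _["accept_rate"] = rate,
                      _["step"] = NumericVector(S.step.begin(), S.step.end()));
}

// Log posterior (and data log-likelihood) of one full parameter assignment,
// used for initialization checks, DIC at the posterior mean, and testing.
// [[Rcpp::export]]
List cpp_log_posterior(int kind, int nsub, IntegerVector sub, NumericVector rt,
                       IntegerVector up, NumericVector F, NumericVector C,
                       NumericVector score, List prior, double eps,
                       NumericVector glx, NumericVector glw,
                       NumericVector state) {
  Sampler S = make_sampler(kind, nsub, sub, rt, up, F, C, score, prior, eps,
                           glx, glw);
  if ((int)state.size() != S.np) stop("state length != number of parameters");
  S.th.assign(state.begin(), state.end());
  double lp = 0.0;
  for (int g = 0; g < S.base; ++g) {
    lp += S.hyper_lp(g, S.th[g]);
    if (!std::isfinite(lp))
      return List::create(_["log_posterior"] = NEG_INF,
                          _["log_lik"] = NEG_INF);
  }
  for (int i = 0; i < nsub; ++i) {
    lp += S.subj_prior_lp(S.th, i);
    if (!std::isfinite(lp))
      return List::create(_["log_posterior"] = NEG_INF,
                          _["log_lik"] = NEG_INF);
  }
  if (!S.init_state())
    return List::create(_["log_posterior"] = NEG_INF, _["log_lik"] = NEG_INF);
  return List::create(_["log_posterior"] = lp + S.sumL,
                      _["log_lik"] = S.sumL);
}
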