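// Hybrid event loops: the simulated (G1) reactions advance by sampling the
// closed-form survival function of the analytically propagated (G2)
// sub-network; reaction identities come from Poisson-marginalized
// propensities.  One loop per built-in model.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rng.h"
#include "kernels.h"

using namespace Rcpp;

struct Counters {
  long events = 0, fast = 0, exact_root = 0, im_fallback = 0;
};

// Solve f(tau) = ln Q(tau) - ln xi = 0 for the monotone-decreasing ln Q.
// Bracket by doubling from the first-order guess, then Illinois
// regula-falsi to 1e-12 relative.  Returns a negative value if no root
// exists below the horizon (G1 effectively silent).
template <typename F>
static double solve_tau(F lnq, double lnxi, double tau_guess) {
  const double horizon = 1e12;
  double lo = 0.0, flo = -lnxi; // lnq(0) = 0
  double hi = (tau_guess > 0 && R_finite(tau_guess)) ? tau_guess : 1.0;
  double fhi = lnq(hi) - lnxi;
  int it = 0;
  while (fhi > 0.0) {
    lo = hi; flo = fhi;
    hi *= 2.0;
    if (hi > horizon || ++it > 100) return -1.0;
    fhi = lnq(hi) - lnxi;
  }
  for (int k = 0; k < 200; ++k) {
    double mid = (hi * flo - lo * fhi) / (flo - fhi);
    if (!R_finite(mid) || mid <= lo || mid >= hi) mid = 0.5 * (lo + hi);
    double fm = lnq(mid) - lnxi;
    if (fm > 0.0) {
      lo = mid; flo = fm;
      fhi *= 0.5; // Illinois weighting keeps superlinear convergence
    } else {
      hi = mid; fhi = fm;
      flo *= 0.5;
    }
    if (hi - lo <= 1e-12 * hi || fm == 0.0) break;
  }
  return 0.5 * (lo + hi);
}

// ---------------- genetic switch ----------------------------------------

struct SwitchPar {
  double a1, a2, b1, b2, r0, r, K, k, q;
};

// linear coefficients a_mu = c + d*n of the six G1 channels at promoter
// state s (0, 1, 2): bind1, unbind1, bind2, unbind2, transcription, decay
static void switch_cd(const SwitchPar &p, int s, double m, double *c,
                      double *d) {
  for (int i = 0; i < 6; ++i) { c[i] = 0; d[i] = 0; }
  if (s == 0) { d[0] = p.a1; c[4] = p.r0; }
  else if (s == 1) { c[1] = p.b1; d[2] = p.a2; c[4] = p.r0; }
  else { c[3] = p.b2; c[4] = p.r; }
  c[5] = p.k * m;
}

// [[Rcpp::export(name = ".hybrid_switch_cpp")]]
List hybrid_switch_cpp(NumericVector par, int s0, double m0, double lam0,
                       double t_final, NumericVector grid, double seed,
                       int n_real, int stream_offset, double eps,
                       int im_mode) {
  SwitchPar p{par[0], par[1], par[2], par[3], par[4],
              par[5], par[6], par[7], par[8]};
  int ntimes = grid.size();
  const int nvar = 5; // S0 S1 S2 m lambda
  NumericVector out((size_t)ntimes * nvar * n_real);
  out.attr("dim") = IntegerVector::create(ntimes, nvar, n_real);
  NumericMatrix cnt(n_real, 4);
  for (int i = 0; i < n_real; ++i) {
    Xoshiro rng((uint64_t)seed, (uint64_t)(stream_offset + i));
    Counters cn;
    int s = s0;
    double m = m0, lam = lam0, t = 0.0;
    int gp = 0;
    double *rec = REAL(out) + (size_t)i * ntimes * nvar;
    auto record_upto = [&](double tnew) {
      while (gp < ntimes && grid[gp] < tnew) {
        double lg = lambda_lin(grid[gp] - t, lam, p.K * m, p.q);
        rec[gp + ntimes * 0] = (s == 0);
        rec[gp + ntimes * 1] = (s == 1);
        rec[gp + ntimes * 2] = (s == 2);
        rec[gp + ntimes * 3] = m;
        rec[gp + ntimes * 4] = lg;
        ++gp;
      }
    };
    while (t < t_final) {
      double Km = p.K * m;
      double qt = p.q + (s == 0 ? p.a1 : 0.0) + (s == 1 ? p.a2 : 0.0);
      double Kt = (s == 1 ? p.b1 : 0.0) + (s == 2 ? p.b2 : 0.0) +
                  (s == 2 ? p.r : p.r0) + (p.K + p.k) * m;
      double b1 = Kt - Km + (qt - p.q) * lam;
      double b2 = (qt - p.q) * (qt * lam - Km);
      if (b1 <= 0.0) { record_upto(t_final + 1); break; }
      double L = std::log(1.0 / rng.unif_open());
      double tau0 = L / b1;
      double denom = b1 - (b2 / b1) * L;
      double tau;
      bool fast = denom > 0.0 &&
                  std::fabs(0.5 * (b2 / b1) * L / denom) < eps / (1.0 + eps);
      if (fast) {
        tau = tau0;
        ++cn.fast;
      } else {
        double lnxi = -L;
        tau = solve_tau([&](double u) {
          return ln_surv_switch(u, lam, Km, p.q, qt, Kt);
        }, lnxi, tau0);
        if (tau < 0.0) { record_upto(t_final + 1); break; }
        ++cn.exact_root;
      }
      double tnew = t + tau;
      record_upto(std::min(tnew, t_final + 1.0));
      if (tnew >= t_final) break;
      lam = lambda_lin(tau, lam, Km, p.q);
      // marginalized reaction probabilities
      double c[6], d[6], pr[6];
      switch_cd(p, s, m, c, d);
      double C = 0, D = 0;
      for (int j = 0; j < 6; ++j) { C += c[j]; D += d[j]; }
      if (D > 0.0) {
        double A = C / D;
        double E = pim_auto(A, lam, im_mode, &cn.im_fallback);
        for (int j = 0; j < 6; ++j)
          pr[j] = d[j] / D + (c[j] - d[j] * A) * E / D;
      } else {
        for (int j = 0; j < 6; ++j) pr[j] = c[j] / C;
      }
      double xi2 = rng.unif(), cum = 0.0;
      int mu = 5;
      for (int j = 0; j < 6; ++j) {
        cum += pr[j];
        if (cum > xi2) { mu = j; break; }
      }
      // apply; protein shifts from binding/unbinding are ignored (the
      // Poisson-preserving default)
      if (mu == 0) s = 1;
      else if (mu == 1) s = 0;
      else if (mu == 2) s = 2;
      else if (mu == 3) s = 1;
      else if (mu == 4) m += 1;
      else m -= 1;
      t = tnew;
      ++cn.events;
    }
    cnt(i, 0) = cn.events; cnt(i, 1) = cn.fast;
    cnt(i, 2) = cn.exact_root; cnt(i, 3) = cn.im_fallback;
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  colnames(cnt) = CharacterVector::create("events", "fast_path",
                                          "exact_root", "im_fallback");
  return List::create(_["states"] = out, _["counters"] = cnt);
}

// ---------------- Griffith oscillator -----------------------------------

struct GriffithPar {
  double al[4], be[4], r, K, k, q, a;
};

// ten G1 channels: bind1, unbind1, ..., bind4, unbind4, transcription,
// decay; propensities linear in the mature conformation count
static void griffith_cd(const GriffithPar &p, int s, double m, double *c,
                        double *d) {
  for (int i = 0; i < 10; ++i) { c[i] = 0; d[i] = 0; }
  if (s < 4) d[2 * s] = p.al[s];         // binding S_s -> S_{s+1}
  if (s > 0) c[2 * s - 1] = p.be[s - 1]; // unbinding S_s -> S_{s-1}
  if (s == 0) c[8] = p.r;
  c[9] = p.k * m;
}

// [[Rcpp::export(name = ".hybrid_griffith_cpp")]]
List hybrid_griffith_cpp(NumericVector par, int d_stages, int s0, double m0,
                         NumericVector lam0, double t_final,
                         NumericVector grid, double seed, int n_real,
                         int stream_offset, double eps, int im_mode,
                         bool qtilde_printed) {
  GriffithPar p;
  for (int i = 0; i < 4; ++i) { p.al[i] = par[i]; p.be[i] = par[4 + i]; }
  p.r = par[8]; p.K = par[9]; p.k = par[10]; p.q = par[11]; p.a = par[12];
  int d = d_stages;
  int ntimes = grid.size();
  const int nvar = 6 + 10; // S0..S4, m, lambda_1..lambda_d (d <= 10 here)
  if (d > 10) stop("compiled Griffith loop supports d <= 10");
  NumericVector out((size_t)ntimes * (6 + d) * n_real);
  out.attr("dim") = IntegerVector::create(ntimes, 6 + d, n_real);
  (void)nvar;
  NumericMatrix cnt(n_real, 4);
  std::vector<double> l0(lam0.begin(), lam0.end());
  for (int i = 0; i < n_real; ++i) {
    Xoshiro rng((uint64_t)seed, (uint64_t)(stream_offset + i));
    Counters cn;
    int s = s0;
    double m = m0, t = 0.0;
    std::vector<double> lam = l0, ltmp;
    int gp = 0;
    double *rec = REAL(out) + (size_t)i * ntimes * (6 + d);
    auto record_upto = [&](double tnew) {
      while (gp < ntimes && grid[gp] < tnew) {
        cascade_eval(grid[gp] - t, lam, p.K * m, p.a, p.q, ltmp);
        for (int j = 0; j < 5; ++j) rec[gp + ntimes * j] = (s == j);
        rec[gp + ntimes * 5] = m;
        for (int j = 0; j < d; ++j) rec[gp + ntimes * (6 + j)] = ltmp[j];
        ++gp;
      }
    };
    while (t < t_final) {
      double Km = p.K * m;
      double qt = (qtilde_printed ? 0.0 : p.q) + (s < 4 ? p.al[s] : 0.0);
      double Kt = (s > 0 ? p.be[s - 1] : 0.0) + (s == 0 ? p.r : 0.0) +
                  (p.K + p.k) * m;
      double b1 = Kt - Km + (qt - p.q) * lam[d - 1];
      double b2 = (qt - p.q) * (qt * lam[d - 1] - p.a * lam[d - 2]);
      if (b1 <= 0.0) { record_upto(t_final + 1); break; }
      double L = std::log(1.0 / rng.unif_open());
      double tau0 = L / b1;
      double denom = b1 - (b2 / b1) * L;
      double tau;
      bool fast = denom > 0.0 &&
                  std::fabs(0.5 * (b2 / b1) * L / denom) < eps / (1.0 + eps);
      if (fast) {
        tau = tau0;
        ++cn.fast;
      } else {
        tau = solve_tau([&](double u) {
          return ln_surv_griffith(u, lam, Km, p.a, p.q, qt, Kt);
        }, -L, tau0);
        if (tau < 0.0) { record_upto(t_final + 1); break; }
        ++cn.exact_root;
      }
      double tnew = t + tau;
      record_upto(std::min(tnew, t_final + 1.0));
      if (tnew >= t_final) break;
      cascade_eval(tau, lam, Km, p.a, p.q, ltmp);
      lam = ltmp;
      double c[10], dd[10], pr[10];
      griffith_cd(p, s, m, c, dd);
      double C = 0, D = 0;
      for (int j = 0; j < 10; ++j) { C += c[j]; D += dd[j]; }
      if (D > 0.0) {
        double A = C / D;
        double E = pim_auto(A, lam[d - 1], im_mode, &cn.im_fallback);
        for (int j = 0; j < 10; ++j)
          pr[j] = dd[j] / D + (c[j] - dd[j] * A) * E / D;
      } else {
        for (int j = 0; j < 10; ++j) pr[j] = c[j] / C;
      }
      double xi2 = rng.unif(), cum = 0.0;
      int mu = 9;
      for (int j = 0; j < 10; ++j) {
        cum += pr[j];
        if (cum > xi2) { mu = j; break; }
      }
      if (mu < 8) {
        // binding (even) or unbinding (odd); mature-count shift ignored
        s = (mu % 2 == 0) ? s + 1 : s - 1;
      } else if (mu == 8) m += 1;
      else m -= 1;
      t = tnew;
      ++cn.events;
    }
    cnt(i, 0) = cn.events; cnt(i, 1) = cn.fast;
    cnt(i, 2) = cn.exact_root; cnt(i, 3) = cn.im_fallback;
    if (i % 16 == 0) Rcpp::checkUserInterrupt();
  }
  colnames(cnt) = CharacterVector::create("events", "fast_path",
                                          "exact_root", "im_fallback");
  return List::create(_["states"] = out, _["counters"] = cnt);
}
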