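// Closed-form propagation of the analytic (G2) sub-network under the Poisson
// ansatz, and the Poisson inverse moments used to marginalize binding
// propensities.  These are the production kernels behind both the R API and
// the compiled hybrid event loops.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include "kernels.h"

using namespace Rcpp;

// <1/(n+a)> under Poisson(lambda), by direct series when exp(-lambda) is
// representable, otherwise by a windowed sum of Poisson weights around the
// mode (terms outside +-12 sd + 50 are below 1e-16 of the total).
double pim_exact(double a, double lambda) {
  if (a <= 0) Rcpp::stop("inverse moment requires a > 0");
  if (lambda < 0) Rcpp::stop("lambda must be >= 0");
  if (lambda == 0) return 1.0 / a;
  if (lambda < 600.0) {
    double term = std::exp(-lambda); // n = 0 weight
    double acc = term / a;
    double n = 0.0;
    for (int i = 1; i < 100000; ++i) {
      n += 1.0;
      term *= lambda / n;
      double c = term / (n + a);
      acc += c;
      if (n > lambda && c < 1e-15 * acc) break;
    }
    return acc;
  }
  double w = 12.0 * std::sqrt(lambda) + 50.0;
  double lo = std::max(0.0, std::floor(lambda - w));
  double hi = std::ceil(lambda + w);
  double acc = 0.0;
  for (double n = lo; n <= hi; n += 1.0) {
    acc += R::dpois(n, lambda, 0) / (n + a);
  }
  return acc;
}

// Three-term moment expansion around the mean (exact through the third
// central moment of the Poisson distribution).
double pim_approx(double a, double lambda) {
  double s = a + lambda;
  return 1.0 / s + lambda / (s * s * s) - lambda / (s * s * s * s);
}

double pim_auto(double a, double lambda, int mode, long *fallback) {
  if (mode == 1) return pim_exact(a, lambda);
  if (a < 1.0 || lambda < 1.0) {
    if (fallback) ++(*fallback);
    return pim_exact(a, lambda);
  }
  return pim_approx(a, lambda);
}

// Mean of a linear birth-death pool: lam' = Km - q lam.
double lambda_lin(double t, double lam0, double Km, double q) {
  if (q == 0.0) return lam0 + Km * t;
  double s = Km / q;
  return (lam0 - s) * std::exp(-q * t) + s;
}

// g' = Kt - q h with h the q->qt twin of lambda and g(0) = lam0.
double g_switch(double t, double lam0, double Km, double q, double qt,
                double Kt) {
  if (qt == 0.0) {
    // h(t) = lam0 + Km t
    return lam0 + Kt * t - q * (lam0 * t + 0.5 * Km * t * t);
  }
  double s = Km / qt;
  return lam0 + (Kt - Km * q / qt) * t +
         (q / qt) * (lam0 - s) * std::expm1(-qt * t);
}

double ln_surv_switch(double tau, double lam0, double Km, double q, double qt,
                      double Kt) {
  double h = lambda_lin(tau, lam0, Km, qt);
  return h - g_switch(tau, lam0, Km, q, qt, Kt);
}

// gamma(j+1, s) / (j! s^(j+1)), entire in s; series branch removes the
// cancellation near s = 0 (and handles s = 0, i.e. a = qlast, exactly).
static double gj_reg(int j, double s) {
  if (std::fabs(s) < 0.5) {
    double acc = 0.0, term = 1.0; // term = (-s)^k / k!
    for (int k = 0; k < 60; ++k) {
      if (k > 0) term *= -s / k;
      double c = term / (j + 1.0 + k);
      acc += c;
      if (k > 4 && std::fabs(c) < 1e-18 * std::fabs(acc)) break;
    }
    double jf = 1.0;
    for (int i = 2; i <= j; ++i) jf *= i;
    return acc / jf;
  }
  double part = 1.0, term = 1.0; // sum_{k<=j} s^k/k!
  for (int k = 1; k <= j; ++k) { term *= s / k; part += term; }
  double res = (1.0 - std::exp(-s) * part);
  return res / std::pow(s, j + 1);
}

void cascade_eval(double t, const std::vector<double> &lam0, double Km,
                  double a, double qlast, std::vector<double> &out) {
  int d = (int)lam0.size();
  out.resize(d);
  double mu = Km / a; // common steady level of the pre-terminal stages
  double eat = std::exp(-a * t);
  // stages i < d: lam_i = mu + e^{-at} sum_{j<i} (lam_{i-j}(0)-mu)(at)^j/j!
  double at = a * t;
  for (int i = 1; i < d; ++i) {
    double acc = 0.0, w = 1.0; // w = (at)^j / j!
    for (int j = 0; j < i; ++j) {
      if (j > 0) w *= at / j;
      acc += (lam0[i - 1 - j] - mu) * w;
    }
    out[i - 1] = mu + eat * acc;
  }
  // terminal stage
  double s = (a - qlast) * t;
  double eqt = std::exp(-qlast * t);
  double acc = lam0[d - 1] - Km / qlast;
  double atp = 1.0; // (at)^{j+1} built up incrementally
  double res = Km / qlast + acc * eqt;
  for (int j = 0; j <= d - 2; ++j) {
    atp *= at;
    res += (lam0[d - 2 - j] - mu) * atp * gj_reg(j, s) * eqt;
  }
  // clamp roundoff negatives (means are >= 0 analytically)
  for (int i = 0; i < d; ++i) {
    if (out[i] < 0) out[i] = 0.0;
  }
  out[d - 1] = res < 0 ? 0.0 : res;
}

// ln Q(tau) = sum_i (h_i - lam_i(0)) - Kt*tau + q * int_0^tau h_d.
// The integral follows from the h cascade itself:
//   int h_1 = (Km tau - (h_1 - h_1(0))) / a
//   int h_j = int h_{j-1} - (h_j - h_j(0)) / a            (1 < j < d)
//   int h_d = (a int h_{d-1} - (h_d - h_d(0))) / qt
double ln_surv_griffith(double tau, const std::vector<double> &lam0,
                        double Km, double a, double q, double qt, double Kt) {
  int d = (int)lam0.size();
  std::vector<double> h;
  cascade_eval(tau, lam0, Km, a, qt, h);
  double I = (Km * tau - (h[0] - lam0[0])) / a;
  for (int j = 1; j < d - 1; ++j) I -= (h[j] - lam0[j]) / a;
  double Id = (a * I - (h[d - 1] - lam0[d - 1])) / qt;
  double acc = 0.0;
  for (int i = 0; i < d; ++i) acc += h[i] - lam0[i];
  return acc - Kt * tau + q * Id;
}

// ---- R-facing wrappers -------------------------------------------------

// [[Rcpp::export(name = ".pim_exact_cpp")]]
double pim_exact_cpp(double a, double lambda) { return pim_exact(a, lambda); }

// [[Rcpp::export(name = ".pim_approx_cpp")]]
double pim_approx_cpp(double a, double lambda) {
  return pim_approx(a, lambda);
}

// [[Rcpp::export(name = ".lambda_lin_cpp")]]
NumericVector lambda_lin_cpp(NumericVector t, double lam0, double Km,
                             double q) {
  NumericVector out(t.size());
  for (int i = 0; i < t.size(); ++i) out[i] = lambda_lin(t[i], lam0, Km, q);
  return out;
}

// [[Rcpp::export(name = ".g_switch_cpp")]]
NumericVector g_switch_cpp(NumericVector t, double lam0, double Km, double q,
                           double qt, double Kt) {
  NumericVector out(t.size());
  for (int i = 0; i < t.size(); ++i)
    out[i] = g_switch(t[i], lam0, Km, q, qt, Kt);
  return out;
}

// [[Rcpp::export(name = ".ln_surv_switch_cpp")]]
NumericVector ln_surv_switch_cpp(NumericVector tau, double lam0, double Km,
                                 double q, double qt, double Kt) {
  NumericVector out(tau.size());
  for (int i = 0; i < tau.size(); ++i)
    out[i] = ln_surv_switch(tau[i], lam0, Km, q, qt, Kt);
  return out;
}

// [[Rcpp::export(name = ".cascade_eval_cpp")]]
NumericMatrix cascade_eval_cpp(NumericVector t, NumericVector lam0, double Km,
                               double a, double qlast) {
  std::vector<double> l0(lam0.begin(), lam0.end()), out;
  NumericMatrix res(t.size(), lam0.size());
  for (int i = 0; i < t.size(); ++i) {
    cascade_eval(t[i], l0, Km, a, qlast, out);
    for (int j = 0; j < (int)out.size(); ++j) res(i, j) = out[j];
  }
  return res;
}

// [[Rcpp::export(name = ".ln_surv_griffith_cpp")]]
NumericVector ln_surv_griffith_cpp(NumericVector tau, NumericVector lam0,
                                   double Km, double a, double q, double qt,
                                   double Kt) {
  std::vector<double> l0(lam0.begin(), lam0.end());
  NumericVector out(tau.size());
  for (int i = 0; i < tau.size(); ++i)
    out[i] = ln_surv_griffith(tau[i], l0, Km, a, q, qt, Kt);
  return out;
}
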