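// Direct-method stochastic simulation of the full network (the exact
// reference).  The network arrives pre-flattened from R: per-reaction
// stoichiometry plus a term table (coef, reaction, up to two species
// factors) encoding mass-action propensities, including the compound
// transcription channel of the switch.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

struct FlatNet {
  int nsp, nrx, nterm;
  std::vector<int> stoich;   // nrx * nsp, row-major by reaction
  std::vector<double> coef;  // per term
  std::vector<int> trx;      // term -> reaction
  std::vector<int> tsp1, tsp2; // species factors, -1 if absent
  std::vector<int> group;    // per reaction: 1 or 2
};

static FlatNet unpack(const List &enc) {
  FlatNet f;
  f.nsp = as<int>(enc["nsp"]);
  IntegerMatrix st = enc["stoich"];
  f.nrx = st.nrow();
  f.stoich.resize((size_t)f.nrx * f.nsp);
  for (int r = 0; r < f.nrx; ++r)
    for (int s = 0; s < f.nsp; ++s) f.stoich[(size_t)r * f.nsp + s] = st(r, s);
  NumericVector cf = enc["coef"];
  IntegerVector tr = enc["trx"], s1 = enc["tsp1"], s2 = enc["tsp2"],
                gr = enc["group"];
  f.nterm = cf.size();
  f.coef.assign(cf.begin(), cf.end());
  f.trx.assign(tr.begin(), tr.end());
  f.tsp1.assign(s1.begin(), s1.end());
  f.tsp2.assign(s2.begin(), s2.end());
  f.group.assign(gr.begin(), gr.end());
  return f;
}

static inline void props(const FlatNet &f, const std::vector<double> &x,
                         std::vector<double> &a) {
  std::fill(a.begin(), a.end(), 0.0);
  for (int t = 0; t < f.nterm; ++t) {
    double v = f.coef[t];
    if (f.tsp1[t] >= 0) v *= x[f.tsp1[t]];
    if (f.tsp2[t] >= 0) v *= x[f.tsp2[t]];
    a[f.trx[t]] += v;
  }
}

// One realization; writes zero-order-hold samples into rec (ntimes x nsp
// block for this realization).
static void ssa_one(const FlatNet &f, const std::vector<double> &init,
                    double t_final, const NumericVector &grid, Xoshiro &rng,
                    double *rec, int ntimes) {
  std::vector<double> x = init, a(f.nrx);
  double t = 0.0;
  int gp = 0;
  for (;;) {
    props(f, x, a);
    double a0 = 0.0;
    for (int r = 0; r < f.nrx; ++r) a0 += a[r];
    double tnew;
    if (a0 <= 0.0) {
      tnew = t_final; // absorbing state: hold to the end
    } else {
      tnew = t + (1.0 / a0) * std::log(1.0 / rng.unif_pos());
    }
    while (gp < ntimes && (grid[gp] < tnew || (a0 <= 0.0 && grid[gp] <= t_final))) {
      for (int s = 0; s < f.nsp; ++s) rec[(size_t)gp + (size_t)ntimes * s] = x[s];
      ++gp;
    }
    if (a0 <= 0.0 || tnew >= t_final) {
      while (gp < ntimes) {
        for (int s = 0; s < f.nsp; ++s) rec[(size_t)gp + (size_t)ntimes * s] = x[s];
        ++gp;
      }
      return;
    }
    double r2a0 = rng.unif() * a0, cum = 0.0;
    int mu = f.nrx - 1;
    for (int r = 0; r < f.nrx; ++r) {
      cum += a[r];
      if (cum > r2a0) { mu = r; break; }
    }
    const int *st = &f.stoich[(size_t)mu * f.nsp];
    for (int s = 0; s < f.nsp; ++s) x[s] += st[s];
    t = tnew;
  }
}

// [[Rcpp::export(name = ".ssa_ensemble_cpp")]]
NumericVector ssa_ensemble_cpp(List enc, NumericVector init, double t_final,
                               NumericVector grid, double seed, int n_real,
                               int stream_offset) {
  FlatNet f = unpack(enc);
  int ntimes = grid.size();
  NumericVector out((size_t)ntimes * f.nsp * n_real);
  out.attr("dim") = IntegerVector::create(ntimes, f.nsp, n_real);
  std::vector<double> x0(init.begin(), init.end());
  for (int i = 0; i < n_real; ++i) {
    Xoshiro rng((uint64_t)seed, (uint64_t)(stream_offset + i));
    ssa_one(f, x0, t_final, grid, rng,
            REAL(out) + (size_t)i * ntimes * f.nsp, ntimes);
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Time of the first group-1 reaction, with the initial count of one species
// optionally drawn from a Poisson distribution (used for survival-curve
// validation).  Returns t_cap + 1 for realizations censored at t_cap.
// [[Rcpp::export(name = ".ssa_first_g1_cpp")]]
NumericVector ssa_first_g1_cpp(List enc, NumericVector init, double t_cap,
                               double seed, int n_real, int poisson_species,
                               double poisson_mean) {
  FlatNet f = unpack(enc);
  NumericVector out(n_real);
  for (int i = 0; i < n_real; ++i) {
    Xoshiro rng((uint64_t)seed, (uint64_t)i);
    std::vector<double> x(init.begin(), init.end()), a(f.nrx);
    if (poisson_species >= 0) {
      // inversion sampling from the Poisson CDF using the stream itself
      double u = rng.unif_open(), c = std::exp(-poisson_mean), F = c;
      int n = 0;
      while (u > F && n < 100000) {
        ++n;
        c *= poisson_mean / n;
        F += c;
      }
      x[poisson_species] = n;
    }
    double t = 0.0, tfirst = t_cap + 1.0;
    for (;;) {
      props(f, x, a);
      double a0 = 0.0;
      for (int r = 0; r < f.nrx; ++r) a0 += a[r];
      if (a0 <= 0.0) break;
      t += (1.0 / a0) * std::log(1.0 / rng.unif_pos());
      if (t > t_cap) break;
      double r2a0 = rng.unif() * a0, cum = 0.0;
      int mu = f.nrx - 1;
      for (int r = 0; r < f.nrx; ++r) {
        cum += a[r];
        if (cum > r2a0) { mu = r; break; }
      }
      if (f.group[mu] == 1) { tfirst = t; break; }
      const int *st = &f.stoich[(size_t)mu * f.nsp];
      for (int s = 0; s < f.nsp; ++s) x[s] += st[s];
    }
    out[i] = tfirst;
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
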