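#ifndef HYBRIDCME_KERNELS_H
#define HYBRIDCME_KERNELS_H

#include <vector>

// Poisson inverse moments <1/(n+a)>
double pim_exact(double a, double lambda);
double pim_approx(double a, double lambda);
// mode 0: three-term expansion with automatic exact fallback when a < 1 or
// lambda < 1; mode 1: always exact series. *fallback counts exact uses in
// mode 0.
double pim_auto(double a, double lambda, int mode, long *fallback);

// Switch-model closed forms (single protein pool, production K*m, decay q)
double lambda_lin(double t, double lam0, double Km, double q);
double g_switch(double t, double lam0, double Km, double q, double qt,
                double Kt);
double ln_surv_switch(double tau, double lam0, double Km, double q, double qt,
                      double Kt);

// Griffith conversion cascade: production K*m into stage 1, conversion rate
// a along stages, last-stage decay qlast. Writes lambda(t) into out.
void cascade_eval(double t, const std::vector<double> &lam0, double Km,
                  double a, double qlast, std::vector<double> &out);
double ln_surv_griffith(double tau, const std::vector<double> &lam0,
                        double Km, double a, double q, double qt, double Kt);

#endif
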