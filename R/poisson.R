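#' Effective decay and loss rates of the switch survival equations
#'
#' At a fixed promoter/mRNA state, the unnormalized G2 distribution of the
#' switch evolves with an effective protein "decay" rate `q_tilde` (protein
#' decay plus the binding channels that consume a protein) and a
#' state-dependent constant loss `K_tilde` (all remaining propensities,
#' including translation):
#' `q_tilde = alpha1*S0 + alpha2*S1 + q` and
#' `K_tilde = beta1*S1 + beta2*S2 + r0*(S0 + S1) + r*S2 + (K + k)*m`.
#' The transcription contribution is the grouped channel's actual
#' propensity (`r0` from the empty or singly occupied promoter, `r` from
#' the doubly occupied one), so the survival function agrees with the
#' lattice oracle in every promoter state.
#'
#' @param state Named vector with `S0`, `S1`, `S2` (one-hot) and `m`.
#' @param params Rates from [switch_params()].
#' @return List with elements `q_tilde` and `K_tilde` (per minute).
#' @export
effective_rates_switch <- function(state, params = switch_params()) {
  with(params, list(
    q_tilde = alpha1 * state[["S0"]] + alpha2 * state[["S1"]] + q,
    K_tilde = beta1 * state[["S1"]] + beta2 * state[["S2"]] +
      r0 * (state[["S0"]] + state[["S1"]]) + r * state[["S2"]] +
      (K + k) * state[["m"]]))
}

#' Effective rates of the Griffith survival equations
#'
#' Analogue of [effective_rates_switch()] for the oscillator:
#' `q_tilde = q + alpha1*S0 + alpha2*S1 + alpha3*S2 + alpha4*S3` (the decay
#' of the mature conformation plus the binding channels that consume it) and
#' `K_tilde = beta1*S1 + ... + beta4*S4 + r*S0 + (K + k)*m`.
#'
#' @param state Named vector with `S0` ... `S4` (one-hot) and `m`.
#' @param params Rates from [griffith_params()].
#' @param qtilde_printed If `TRUE`, omit the `+ q` term from `q_tilde`
#'   (a documented variant; the default form is the one that satisfies the
#'   unnormalized master equation, as checked against the lattice oracle).
#' @return List with `q_tilde` and `K_tilde`.
#' @export
effective_rates_griffith <- function(state, params = griffith_params(),
                                     qtilde_printed = FALSE) {
  with(params, list(
    q_tilde = (if (qtilde_printed) 0 else q) +
      alpha1 * state[["S0"]] + alpha2 * state[["S1"]] +
      alpha3 * state[["S2"]] + alpha4 * state[["S3"]],
    K_tilde = beta1 * state[["S1"]] + beta2 * state[["S2"]] +
      beta3 * state[["S3"]] + beta4 * state[["S4"]] + r * state[["S0"]] +
      (K + k) * state[["m"]]))
}

#' Poisson mean of the switch protein pool
#'
#' Closed-form solution of `lambda' = K*m - q*lambda`:
#' `lambda(t) = (lambda0 - K*m/q) exp(-q t) + K*m/q`, with the continuous
#' limit `lambda0 + K*m*t` when `q = 0`.
#'
#' @param t Time(s) since the last simulated event (minutes).
#' @param lambda0 Initial Poisson mean.
#' @param K,m,q Translation rate, mRNA count, protein decay rate.
#' @return `lambda(t)`, vectorized over `t`.
#' @export
lambda_switch <- function(t, lambda0, K, m, q) {
  stopifnot(all(t >= 0), lambda0 >= 0)
  .lambda_lin_cpp(as.numeric(t), lambda0, K * m, q)
}

#' Auxiliary survival solutions h(t) and g(t) for the switch
#'
#' `h` follows the same linear equation as the Poisson mean but with the
#' effective decay `q_tilde`; `g` integrates `g' = K_tilde - q*h` from
#' `g(0) = lambda0`. The survival probability of the simulated reactions is
#' `Q(tau) = exp(h(tau) - g(tau))`.
#'
#' @inheritParams lambda_switch
#' @param state Named vector with `S0`, `S1`, `S2`, `m`.
#' @param params Rates from [switch_params()].
#' @return List with vectors `h` and `g`.
#' @export
h_g_switch <- function(t, lambda0, state, params = switch_params()) {
  er <- effective_rates_switch(state, params)
  Km <- params$K * state[["m"]]
  list(h = .lambda_lin_cpp(as.numeric(t), lambda0, Km, er$q_tilde),
       g = .g_switch_cpp(as.numeric(t), lambda0, Km, params$q, er$q_tilde,
                         er$K_tilde))
}

#' Log survival probability of the simulated switch reactions
#'
#' `ln Q(tau) = h(tau) - g(tau)`; `Q(0) = 1` by construction and `Q` decays
#' monotonically whenever the expected simulated propensity is positive.
#'
#' @inheritParams h_g_switch
#' @param tau Waiting time(s), minutes.
#' @return `ln Q(tau)` (use [survival_switch()] for `Q` itself).
#' @export
log_survival_switch <- function(tau, lambda0, state,
                                params = switch_params()) {
  er <- effective_rates_switch(state, params)
  .ln_surv_switch_cpp(as.numeric(tau), lambda0, params$K * state[["m"]],
                      params$q, er$q_tilde, er$K_tilde)
}

#' @rdname log_survival_switch
#' @export
survival_switch <- function(tau, lambda0, state, params = switch_params()) {
  exp(log_survival_switch(tau, lambda0, state, params))
}

#' Poisson means of the Griffith conversion cascade
#'
#' Closed-form solution of the linear cascade
#' `lambda1' = K*m - a*lambda1`, `lambdai' = a*(lambda(i-1) - lambdai)`,
#' `lambdad' = a*lambda(d-1) - q*lambdad`: exponential-polynomial sums for
#' the pre-terminal stages and an incomplete-gamma sum for the terminal one.
#' The confluent case `a = q` is evaluated by the series limit (no small
#' offset is needed).
#'
#' @param t Time(s), minutes.
#' @param lambda0 Vector of initial means (length `d >= 2`).
#' @param K,m mRNA translation rate and count (production `K*m` into stage 1).
#' @param a Conversion rate; `q` terminal decay rate.
#' @param q Terminal-stage decay rate.
#' @return Matrix `length(t) x d` of means (a vector if `length(t) == 1`).
#' @export
lambda_griffith <- function(t, lambda0, K, m, a, q) {
  stopifnot(length(lambda0) >= 2, all(t >= 0), all(lambda0 >= 0),
            a > 0, q > 0)
  out <- .cascade_eval_cpp(as.numeric(t), as.numeric(lambda0), K * m, a, q)
  if (length(t) == 1L) drop(out) else out
}

#' Survival auxiliaries for the Griffith model
#'
#' The `h` cascade equals the `lambda` cascade except that the terminal
#' stage decays with `q_tilde`; `g` integrates `g' = K_tilde - q*h_d` from
#' `g(0) = sum(lambda0)` so that `Q(0) = 1` exactly, and
#' `ln Q(tau) = sum(h(tau)) - g(tau)`. The integral of `h_d` is evaluated
#' in closed form through the cascade's own balance relations.
#'
#' @param t Time(s), minutes.
#' @param lambda0 Initial means (length `d`).
#' @param state Named vector with `S0` ... `S4`, `m`.
#' @param params Rates from [griffith_params()].
#' @param qtilde_printed Passed to [effective_rates_griffith()].
#' @return For `g_griffith`, the vector `g(t)`; for
#'   `log_survival_griffith`/`survival_griffith`, `ln Q` or `Q`.
#' @export
g_griffith <- function(t, lambda0, state, params = griffith_params(),
                       qtilde_printed = FALSE) {
  rowSums(h_griffith(t, lambda0, state, params, qtilde_printed,
                     drop = FALSE)) -
    log_survival_griffith(t, lambda0, state, params, qtilde_printed)
}

#' @rdname g_griffith
#' @param drop Return a vector when `length(t) == 1`.
#' @export
h_griffith <- function(t, lambda0, state, params = griffith_params(),
                       qtilde_printed = FALSE, drop = TRUE) {
  er <- effective_rates_griffith(state, params, qtilde_printed)
  out <- .cascade_eval_cpp(as.numeric(t), as.numeric(lambda0),
                           params$K * state[["m"]], params$a, er$q_tilde)
  if (drop && length(t) == 1L) drop(out) else out
}

#' @rdname g_griffith
#' @param tau Waiting time(s), minutes.
#' @export
log_survival_griffith <- function(tau, lambda0, state,
                                  params = griffith_params(),
                                  qtilde_printed = FALSE) {
  er <- effective_rates_griffith(state, params, qtilde_printed)
  .ln_surv_griffith_cpp(as.numeric(tau), as.numeric(lambda0),
                        params$K * state[["m"]], params$a, params$q,
                        er$q_tilde, er$K_tilde)
}

#' @rdname g_griffith
#' @export
survival_griffith <- function(tau, lambda0, state,
                              params = griffith_params(),
                              qtilde_printed = FALSE) {
  exp(log_survival_griffith(tau, lambda0, state, params, qtilde_printed))
}

#' Poisson inverse moment
#'
#' The expectation `<1/(n + a)>` under `n ~ Poisson(lambda)`, computed by
#' adaptive series summation (term-ratio stopping at 1e-15, switching to a
#' windowed sum around the mode for large `lambda`). Analytically this
#' equals `exp(-lambda) * B(a, lambda)` with
#' `B(a, b) = sum_n b^n / ((a + n) n!)`, the incomplete-gamma identity
#' `B(a,b) = (-b)^{-a} [Gamma(a) - Gamma(a, -b)]`; the series avoids the
#' branch-cut hazards of evaluating the incomplete gamma at a negative
#' argument.
#'
#' @param a Positive shift (non-integer allowed); `a <= 0` is rejected
#'   because the summation lattice hits the pole.
#' @param lambda Poisson mean, `>= 0`.
#' @return `<1/(n + a)>`, vectorized over both arguments.
#' @export
poisson_inverse_moment <- function(a, lambda) {
  if (any(a <= 0)) stop("a must be > 0", call. = FALSE)
  if (any(lambda < 0)) stop("lambda must be >= 0", call. = FALSE)
  mapply(.pim_exact_cpp, a, lambda)
}

#' Moment-expansion approximation of the Poisson inverse moment
#'
#' Three-term expansion of `<1/(n + a)>` around `n = lambda`:
#' `1/(a+lambda) + lambda/(a+lambda)^3 - lambda/(a+lambda)^4`, exact
#' through the third central moment. Inaccurate for small `a` or `lambda`
#' (the hybrid loop therefore falls back to the exact series when `a < 1`
#' or `lambda < 1`).
#'
#' @inheritParams poisson_inverse_moment
#' @export
approx_inverse_moment <- function(a, lambda) {
  s <- a + lambda
  1 / s + lambda / s^3 - lambda / s^4
}

#' First-order waiting-time sample with quadratic error control
#'
#' Expanding `ln Q(tau) ~ -b1*tau + b2*tau^2/2` around `tau = 0`, the
#' first-order root of `Q(tau) = xi1` is `tau0 = ln(1/xi1)/b1` and the
#' relative size of the second-order correction is
#' `ratio = (b2/b1) L / (2 (b1 - (b2/b1) L))` with `L = ln(1/xi1)`. The fast
#' path is accepted when `|ratio| < eps`; otherwise the caller must solve
#' the exact survival equation. `b1` equals the summed simulated-reaction
#' propensity with the analytic species replaced by its current mean.
#'
#' @param xi1 Uniform variate in (0, 1).
#' @param b1 First log-survival derivative (must be positive for the fast
#'   path; otherwise the fallback is forced).
#' @param b2 Second-order coefficient.
#' @param eps Acceptance threshold (default 0.001). The bound is applied
#'   conservatively to `|tau1| / (tau0 + tau1)`, i.e. acceptance requires
#'   `|ratio| < eps / (1 + eps)`, so that `eps` bounds the fast path's
#'   relative error against the corrected root rather than only its
#'   first-order estimate.
#' @return List with `tau0`, `ratio`, `fast_ok`, and `tau` (`tau0` when
#'   accepted, `NA` otherwise).
#' @export
fast_tau <- function(xi1, b1, b2, eps = 0.001) {
  stopifnot(xi1 > 0, xi1 < 1, eps > 0)
  if (b1 <= 0) {
    return(list(tau0 = NA_real_, ratio = Inf, fast_ok = FALSE,
                tau = NA_real_))
  }
  L <- log(1 / xi1)
  tau0 <- L / b1
  denom <- b1 - (b2 / b1) * L
  ratio <- if (denom <= 0) Inf else 0.5 * (b2 / b1) * L / denom
  ok <- is.finite(ratio) && abs(ratio) < eps / (1 + eps)
  list(tau0 = tau0, ratio = ratio, fast_ok = ok,
       tau = if (ok) tau0 else NA_real_)
}
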