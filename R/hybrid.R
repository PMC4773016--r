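#' Hybrid simulation state
#'
#' The state carried between simulated events: the simulated (G1) species --
#' promoter occupancy and mRNA count -- plus the Poisson mean vector of the
#' analytic (G2) species and the clock.
#'
#' @param network A built-in `reaction_network`.
#' @param promoter Number of bound proteins (0..2 for the switch, 0..4 for
#'   the oscillator).
#' @param m mRNA copy number.
#' @param lambda Poisson mean(s) of the analytic species (scalar for the
#'   switch, length-`d` vector for the oscillator). Defaults to zero.
#' @param t Current time, minutes.
#' @return Object of class `hybrid_state`.
#' @export
hybrid_state <- function(network, promoter = 0, m = 0, lambda = NULL,
                         t = 0) {
  npr <- if (network$model == "switch") 2L else 4L
  stopifnot(promoter %in% 0:npr, m >= 0, m == round(m))
  if (is.null(lambda)) {
    lambda <- if (network$model == "switch") 0 else numeric(network$d)
  }
  stopifnot(all(lambda >= 0),
            length(lambda) == if (network$model == "switch") 1L else network$d)
  structure(list(network = network, promoter = as.integer(promoter),
                 m = m, lambda = as.numeric(lambda), t = t),
            class = "hybrid_state")
}

## one-hot promoter + m, as a named vector
g1_state_vector <- function(state) {
  npr <- if (state$network$model == "switch") 2L else 4L
  v <- setNames(numeric(npr + 2L), c(paste0("S", 0:npr), "m"))
  v[paste0("S", state$promoter)] <- 1
  v["m"] <- state$m
  v
}

#' @exportS3Method base::print
print.hybrid_state <- function(x, ...) {
  cat("<hybrid_state>", x$network$model, "| promoter S", x$promoter,
      "| m =", x$m, "| lambda =",
      paste(signif(x$lambda, 4), collapse = ", "), "| t =", x$t, "\n")
  invisible(x)
}

#' Sample the next simulated-event waiting time
#'
#' Solves `Q(tau) = xi1` for the closed-form survival function of the
#' current state. The first-order fast path ([fast_tau()]) is used when its
#' quadratic error-control ratio passes `eps`; otherwise the monotone
#' survival equation is solved by bracketed root finding to 1e-10 relative
#' tolerance.
#'
#' @param state A `hybrid_state`.
#' @param xi1 Uniform variate in (0, 1).
#' @param eps Fast-path threshold, see [fast_tau()].
#' @param force_exact Skip the fast path.
#' @return List with `tau` (`Inf` if the simulated group is silent and no
#'   root exists below the horizon), and the bookkeeping fields `fast`
#'   (logical) and `tau0`.
#' @export
sample_tau <- function(state, xi1, eps = 0.001, force_exact = FALSE) {
  stopifnot(xi1 > 0, xi1 < 1)
  net <- state$network
  p <- net$params
  sv <- g1_state_vector(state)
  if (net$model == "switch") {
    er <- effective_rates_switch(sv, p)
    Km <- p$K * state$m
    lam <- state$lambda
    b1 <- er$K_tilde - Km + (er$q_tilde - p$q) * lam
    b2 <- (er$q_tilde - p$q) * (er$q_tilde * lam - Km)
    lnq <- function(u) log_survival_switch(u, lam, sv, p)
  } else {
    er <- effective_rates_griffith(sv, p)
    Km <- p$K * state$m
    d <- net$d
    lam <- state$lambda
    b1 <- er$K_tilde - Km + (er$q_tilde - p$q) * lam[d]
    b2 <- (er$q_tilde - p$q) * (er$q_tilde * lam[d] - p$a * lam[d - 1])
    lnq <- function(u) log_survival_griffith(u, lam, sv, p)
  }
  if (b1 <= 0) return(list(tau = Inf, fast = FALSE, tau0 = NA_real_))
  ft <- fast_tau(xi1, b1, b2, eps)
  if (!force_exact && ft$fast_ok) {
    return(list(tau = ft$tau0, fast = TRUE, tau0 = ft$tau0))
  }
  lnxi <- log(xi1)
  f <- function(u) lnq(u) - lnxi
  hi <- max(ft$tau0, 1e-12)
  it <- 0
  while (f(hi) > 0) {
    hi <- 2 * hi
    it <- it + 1
    if (hi > 1e12 || it > 100) {
      return(list(tau = Inf, fast = FALSE, tau0 = ft$tau0))
    }
  }
  root <- uniroot(f, c(0, hi), tol = 1e-12 * max(hi, 1))$root
  list(tau = root, fast = FALSE, tau0 = ft$tau0)
}

## Generic next-reaction marginalization: each G1 propensity is linear in
## the one analytic species entering G1, a_mu(n) = c_mu + d_mu n.  With
## n ~ Poisson(lambda) and total a(n) = C + D n = D (n + A),
##   p_mu = d_mu / D + (c_mu - d_mu A) <1/(n + A)> / D,
## exactly; when D = 0 the probabilities are the constant ratios c_mu / C.
marginal_probs_linear <- function(cvec, dvec, lambda,
                                  inverse_moment = c("auto", "exact",
                                                     "series", "approx")) {
  inverse_moment <- match.arg(inverse_moment)
  cvec <- unname(cvec); dvec <- unname(dvec)
  C <- sum(cvec); D <- sum(dvec)
  if (D <= 0) {
    if (C <= 0) stop("all marginalized propensities are zero")
    return(cvec / C)
  }
  A <- C / D
  E <- switch(inverse_moment,
              exact = , series = poisson_inverse_moment(A, lambda),
              approx = approx_inverse_moment(A, lambda),
              auto = if (A < 1 || lambda < 1) {
                poisson_inverse_moment(A, lambda)
              } else {
                approx_inverse_moment(A, lambda)
              })
  dvec / D + (cvec - dvec * A) * E / D
}

#' Marginalized reaction probabilities of the switch
#'
#' Probability that each of the six simulated channels (bind, unbind, bind,
#' unbind, transcription, mRNA decay) is the next to fire, marginalized
#' over the Poisson-distributed protein count at the event time. Computed
#' by the exact linear-propensity marginalization, which reproduces the
#' per-promoter-state closed forms with `a_i` shifts `a1 = (r0 + k m)/alpha1`
#' (empty promoter) and `a2 = (beta1 + r0 + k m)/alpha2` (singly occupied).
#'
#' @param state A `hybrid_state` whose `lambda` has already been advanced
#'   to the event time.
#' @param inverse_moment `"exact"` for the series inverse moment, `"approx"`
#'   for the three-term expansion, `"auto"` (default) for the expansion
#'   with exact fallback when `a < 1` or `lambda < 1`.
#' @return Probability vector of length 6 (sums to 1).
#' @export
reaction_probs_switch <- function(state, inverse_moment = "auto") {
  cd <- g1_linear_coefs(state$network, g1_state_vector(state))
  marginal_probs_linear(cd$c, cd$d, state$lambda, inverse_moment)
}

#' Marginalized reaction probabilities of the Griffith model
#'
#' As [reaction_probs_switch()], for the ten oscillator channels (bind1,
#' unbind1, ..., bind4, unbind4, transcription, mRNA decay), with the
#' mature conformation's marginal Poisson(`lambda_d`). The `a_i` shifts
#' follow from the reaction set: `a1 = (r + k m)/alpha1`,
#' `a_{i+1} = (beta_i + k m)/alpha_{i+1}`.
#'
#' @inheritParams reaction_probs_switch
#' @param as_printed If `TRUE`, use the variant coefficient set
#'   `a1 = k m / alpha1`, `a4 = (k m + beta4)/alpha4` and transcription
#'   weight independent of the binding shift (documented variant; it does
#'   not satisfy the brute-force marginalization and is provided for
#'   comparison only).
#' @return Probability vector of length 10.
#' @export
reaction_probs_griffith <- function(state, inverse_moment = "auto",
                                    as_printed = FALSE) {
  net <- state$network
  cd <- g1_linear_coefs(net, g1_state_vector(state))
  lam_d <- state$lambda[net$d]
  if (!as_printed) {
    return(marginal_probs_linear(cd$c, cd$d, lam_d, inverse_moment))
  }
  ## printed variant: evaluate the published per-state expressions
  p <- net$params
  s <- state$promoter
  m <- state$m
  km <- p$k * m
  al <- unlist(p[paste0("alpha", 1:4)])
  be <- unlist(p[paste0("beta", 1:4)])
  a_shift <- c(km / al[1], (km + be[1]) / al[2], (km + be[2]) / al[3],
               (km + be[4]) / al[4])
  im <- function(a) poisson_inverse_moment(a, lam_d)
  pr <- numeric(10)
  if (s < 4) {
    pr[2 * s + 1] <- 1 - a_shift[s + 1] * im(a_shift[s + 1])
    if (s > 0) pr[2 * s] <- be[s] / al[s + 1] * im(a_shift[s + 1])
    if (s == 0) pr[9] <- p$r / al[1] * im(a_shift[1])
    pr[10] <- km / al[s + 1] * im(a_shift[s + 1])
  } else {
    pr[8] <- be[4] / (be[4] + km)
    pr[10] <- km / (km + be[4])
  }
  pr
}

#' Select the next simulated reaction
#'
#' Smallest index whose cumulative probability exceeds `xi2`.
#'
#' @param p Probability vector (non-negative, summing to 1 within 1e-9
#'   when exact inverse moments are used).
#' @param xi2 Uniform variate in [0, 1).
#' @return 1-based reaction index.
#' @export
select_next_reaction <- function(p, xi2) {
  stopifnot(all(p >= -1e-12), xi2 >= 0, xi2 < 1)
  idx <- which(cumsum(p) > xi2)
  unname(if (length(idx) == 0L) max(which(p > 0)) else idx[1L])
}

#' Distribution shifts for simulated reactions that touch analytic species
#'
#' When a simulated reaction changes an analytic species by +w the new
#' initial distribution is the old one shifted up (`P'(n) = P(n - w)`);
#' when it removes w copies the mass-conserving down-shift with pile-up at
#' zero applies: `P'(0) = P(0) + ... + P(w)`, `P'(n) = P(n + w)` for
#' `n >= 1`. The default hybrid mode skips these modifications (binding
#' and unbinding move a single protein and the binding rates are small),
#' keeping the distribution exactly Poisson; the operators are exposed for
#' the exact validation mode.
#'
#' @param p Probability vector over the lattice `0..(length(p) - 1)`.
#' @param w Positive integer shift.
#' @return Shifted probability vector (same length; up-shift mass falling
#'   off the lattice end is an error).
#' @export
shift_distribution_down <- function(p, w = 1) {
  stopifnot(w >= 1, w == round(w))
  nmax <- length(p) - 1L
  out <- numeric(length(p))
  keep <- seq_len(nmax - w + 1L) # new indices 1..nmax-w  (counts 1..)
  out[1L] <- sum(p[seq_len(w + 1L)])
  if (nmax > w) out[1L + seq_len(nmax - w)] <- p[(1L + w) + seq_len(nmax - w)]
  out
}

#' @rdname shift_distribution_down
#' @export
shift_distribution_up <- function(p, w = 1) {
  stopifnot(w >= 1, w == round(w))
  if (any(tail(p, w) > 1e-12)) {
    stop("up-shift would push probability mass off the lattice; enlarge it")
  }
  c(numeric(w), head(p, length(p) - w))
}

#' Apply a simulated reaction and reset the analytic distribution
#'
#' Advances the clock by `tau`, advances the Poisson mean(s) to the event
#' time via the closed forms, applies the reaction's stoichiometry to the
#' simulated species, and (in the default Poisson-preserving mode) carries
#' the advanced mean unchanged as the new initial condition -- the
#' single-protein shift of binding/unbinding events is ignored, as the
#' small binding rates justify.
#'
#' @param state A `hybrid_state`.
#' @param mu Index of the simulated reaction (in the model's channel
#'   ordering).
#' @param tau Sampled waiting time.
#' @return The updated `hybrid_state`.
#' @export
apply_reaction_and_reset <- function(state, mu, tau) {
  net <- state$network
  p <- net$params
  if (net$model == "switch") {
    stopifnot(mu %in% 1:6)
    state$lambda <- lambda_switch(tau, state$lambda, p$K, state$m, p$q)
    state$promoter <- state$promoter +
      c(1L, -1L, 1L, -1L, 0L, 0L)[mu]
    state$m <- state$m + c(0, 0, 0, 0, 1, -1)[mu]
  } else {
    stopifnot(mu %in% 1:10)
    state$lambda <- lambda_griffith(tau, state$lambda, p$K, state$m, p$a,
                                    p$q)
    if (mu <= 8) {
      state$promoter <- state$promoter + if (mu %% 2 == 1) 1L else -1L
    } else {
      state$m <- state$m + if (mu == 9) 1 else -1
    }
  }
  npr <- if (net$model == "switch") 2L else 4L
  stopifnot(state$promoter >= 0, state$promoter <= npr, state$m >= 0)
  state$t <- state$t + tau
  state
}

#' Run the hybrid simulation
#'
#' The production event loop (compiled): sample the waiting time from the
#' closed-form survival function (first-order fast path with quadratic
#' error control, exact bracketed root otherwise), pick the simulated
#' reaction from the Poisson-marginalized probabilities, apply it, and
#' carry the advanced Poisson mean(s) forward. Records the simulated
#' species and the analytic means on the grid (zero-order hold for the
#' simulated part; the means evolve continuously between events).
#'
#' @inheritParams simulate_ssa
#' @param init A `hybrid_state` (defaults to empty promoter, no mRNA,
#'   zero means).
#' @param eps Fast-path threshold (see [fast_tau()]).
#' @param inverse_moment `"auto"` (three-term expansion, exact fallback
#'   when `a < 1` or `lambda < 1`) or `"exact"`.
#' @param qtilde_printed Griffith only: use the variant effective decay
#'   without the `+ q` term (see [effective_rates_griffith()]).
#' @return An `ensemble_states` array `[time, variable, realization]`
#'   (promoter indicators, `m`, and the Poisson mean(s) `lambda*`), with a
#'   `counters` attribute: per-realization events, fast-path and
#'   exact-root counts, and exact-inverse-moment fallbacks.
#' @examples
#' net <- switch_network()
#' h <- simulate_hybrid(net, t_final = 50, seed = 1,
#'                      record_times = seq(0, 50, 5))
#' h[, "m", 1]
#' @export
simulate_hybrid <- function(network, init = hybrid_state(network), t_final,
                            seed,
                            record_times = seq(0, t_final, length.out = 101),
                            n_real = 1, stream_offset = 0, eps = 0.001,
                            inverse_moment = c("auto", "exact"),
                            qtilde_printed = FALSE) {
  stopifnot(t_final > 0, !is.unsorted(record_times),
            all(record_times >= 0), all(record_times <= t_final),
            eps > 0, inherits(init, "hybrid_state"))
  inverse_moment <- match.arg(inverse_moment)
  im_mode <- if (inverse_moment == "exact") 1L else 0L
  p <- network$params
  if (network$model == "switch") {
    par <- unlist(p[c("alpha1", "alpha2", "beta1", "beta2", "r0", "r", "K",
                      "k", "q")])
    res <- .hybrid_switch_cpp(par, init$promoter, init$m, init$lambda,
                              t_final, as.numeric(record_times), seed,
                              as.integer(n_real), as.integer(stream_offset),
                              eps, im_mode)
    vars <- c("S0", "S1", "S2", "m", "lambda")
  } else {
    par <- unlist(p[c("alpha1", "alpha2", "alpha3", "alpha4", "beta1",
                      "beta2", "beta3", "beta4", "r", "K", "k", "q", "a")])
    res <- .hybrid_griffith_cpp(par, network$d, init$promoter, init$m,
                                init$lambda, t_final,
                                as.numeric(record_times), seed,
                                as.integer(n_real),
                                as.integer(stream_offset), eps, im_mode,
                                qtilde_printed)
    vars <- c(paste0("S", 0:4), "m", paste0("lambda", seq_len(network$d)))
  }
  out <- res$states
  dimnames(out) <- list(NULL, vars, NULL)
  structure(out, times = as.numeric(record_times), model = network$model,
            seed = seed, counters = res$counters,
            class = "ensemble_states")
}

#' Pure-R reference hybrid loop
#'
#' Slow single-realization loop built from the exported per-step
#' operations ([sample_tau()], the reaction-probability functions,
#' [select_next_reaction()], [apply_reaction_and_reset()]) using R's own
#' RNG. Used to cross-validate the compiled loop; not meant for
#' production ensembles.
#'
#' @inheritParams simulate_hybrid
#' @return Matrix `[time, variable]` like one slice of
#'   [simulate_hybrid()]'s output.
#' @export
run_hybrid_r <- function(network, init = hybrid_state(network), t_final,
                         seed,
                         record_times = seq(0, t_final, length.out = 101),
                         eps = 0.001, inverse_moment = "auto") {
  set.seed(seed)
  st <- init
  p <- network$params
  d <- if (network$model == "switch") 1L else network$d
  vars <- if (network$model == "switch") {
    c("S0", "S1", "S2", "m", "lambda")
  } else {
    c(paste0("S", 0:4), "m", paste0("lambda", seq_len(d)))
  }
  out <- matrix(NA_real_, length(record_times), length(vars),
                dimnames = list(NULL, vars))
  record <- function(st, upto) {
    todo <- which(is.na(out[, 1]) & record_times < upto)
    for (g in todo) {
      lam_g <- if (network$model == "switch") {
        lambda_switch(record_times[g] - st$t, st$lambda, p$K, st$m, p$q)
      } else {
        lambda_griffith(record_times[g] - st$t, st$lambda, p$K, st$m, p$a,
                        p$q)
      }
      npr <- if (network$model == "switch") 2L else 4L
      out[g, ] <<- c(as.numeric(0:npr == st$promoter), st$m, lam_g)
    }
  }
  while (st$t < t_final) {
    ts <- sample_tau(st, runif(1), eps = eps)
    tnew <- st$t + ts$tau
    record(st, min(tnew, t_final + 1))
    if (tnew >= t_final) break
    pr <- if (network$model == "switch") {
      reaction_probs_switch(
        within_advance(st, ts$tau), inverse_moment)
    } else {
      reaction_probs_griffith(
        within_advance(st, ts$tau), inverse_moment)
    }
    mu <- select_next_reaction(pr, runif(1))
    st <- apply_reaction_and_reset(st, mu, ts$tau)
  }
  out
}

## advance only the Poisson mean to the event time (for computing reaction
## probabilities at tau before committing the event)
within_advance <- function(state, tau) {
  p <- state$network$params
  state$lambda <- if (state$network$model == "switch") {
    lambda_switch(tau, state$lambda, p$K, state$m, p$q)
  } else {
    lambda_griffith(tau, state$lambda, p$K, state$m, p$a, p$q)
  }
  state
}
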