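## Exact validation mode: one hybrid step with the analytic distribution
## carried as an explicit truncated vector and propagated by the lattice
## oracle, including the distribution shifts that the production
## (Poisson-preserving) mode ignores.  Slow by construction; used to
## quantify what the default mode approximates.

#' One exact-mode hybrid step
#'
#' Samples the waiting time by root-finding on the oracle-integrated
#' survival function (no Poisson ansatz), picks the reaction from the
#' brute-force marginalized probabilities, applies its stoichiometry to
#' the simulated species, advances the distribution with the normalized
#' master equation, and applies the up-/down-shift when the reaction
#' moves copies of an analytic species.
#'
#' @param network A built-in `reaction_network` (the switch is the
#'   intended target; the oscillator works for small `d` only).
#' @param g1_state Named one-hot promoter + `m` vector.
#' @param dist A `truncated_distribution` over the analytic species.
#' @param xi1,xi2 Uniform variates in (0, 1).
#' @param tau_max Root-search horizon.
#' @return List `tau`, `mu` (G1 reaction index), `g1_state`, `dist`
#'   (post-event), `survival_check` (|Q(tau) - xi1|).
#' @export
hybrid_step_exact <- function(network, g1_state, dist, xi1, xi2,
                              tau_max = 500) {
  stopifnot(xi1 > 0, xi1 < 1)
  surv <- function(tt) integrate_Q(network, g1_state, dist, tt)$survival
  f <- function(tt) surv(tt) - xi1
  hi <- 1
  while (f(hi) > 0) {
    hi <- 2 * hi
    if (hi > tau_max) stop("no simulated event before the horizon")
  }
  tau <- uniroot(f, c(0, hi), tol = 1e-10)$root
  pt <- integrate_P(network, g1_state, dist, tau)
  pr <- marginal_reaction_probs(network, g1_state, pt)
  mu <- select_next_reaction(pr / sum(pr), xi2)
  rx1 <- Filter(function(r) r$group == "G1", network$reactions)
  st <- rx1[[mu]]$stoich
  g1 <- names(g1_state)
  new_g1 <- g1_state + st[g1]
  newp <- pt$p
  for (sp in pt$species) {
    w <- st[[sp]]
    if (w > 0) newp <- shift_nd(newp, pt$nmax, pt$species, sp, w, up = TRUE)
    if (w < 0) newp <- shift_nd(newp, pt$nmax, pt$species, sp, -w,
                                up = FALSE)
  }
  list(tau = tau, mu = mu, g1_state = new_g1,
       dist = new_truncated(newp, pt$nmax, pt$species),
       survival_check = abs(surv(tau) - xi1))
}

## apply shift_distribution_up / _down along one axis of the joint lattice
shift_nd <- function(p, nmax, species, sp, w, up) {
  fun <- if (up) shift_distribution_up else shift_distribution_down
  if (length(nmax) == 1L) return(fun(p, w))
  arr <- array(p, nmax + 1L)
  ax <- match(sp, species)
  rest <- setdiff(seq_along(nmax), ax)
  out <- apply(arr, rest, fun, w = w)
  ## apply() puts the shifted axis first; restore the original order
  perm <- order(c(ax, rest))
  as.vector(aperm(array(out, c(nmax[ax] + 1L, nmax[rest] + 1L)), perm))
}

#' Short exact-mode hybrid run
#'
#' Chains [hybrid_step_exact()] from a Poisson initial distribution,
#' recording every event. Intended for validating the production mode on
#' short horizons, not for production ensembles.
#'
#' @inheritParams hybrid_step_exact
#' @param lambda0 Initial Poisson mean(s) of the analytic species.
#' @param t_final Stop time, minutes.
#' @param seed Seed for R's RNG.
#' @return Data frame with one row per event: `t`, `mu`, the simulated
#'   state after the event, and the mean of the analytic distribution.
#' @export
run_hybrid_exact <- function(network, g1_state, lambda0, t_final, seed) {
  set.seed(seed)
  dist <- truncated_poisson(network, lambda0)
  t <- 0
  rows <- list()
  while (t < t_final) {
    step <- tryCatch(
      hybrid_step_exact(network, g1_state, dist, runif(1), runif(1),
                        tau_max = 4 * t_final),
      error = function(e) NULL)
    if (is.null(step)) break
    t <- t + step$tau
    if (t >= t_final) break
    g1_state <- step$g1_state
    dist <- step$dist
    rows[[length(rows) + 1L]] <-
      c(t = t, mu = step$mu, g1_state, mean_n = sum(lattice_mean(dist)))
  }
  as.data.frame(do.call(rbind, rows))
}
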