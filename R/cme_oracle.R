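## Truncated-state-space integration of the analytic sub-network's master
## equation at fixed simulated state: the brute-force verifier for every
## closed form in the package.  The joint lattice grows geometrically with
## the number of analytic species, so the oscillator is only integrated
## here for small d; the production model is verified component-wise and
## against the full SSA instead.

#' Truncated distribution over the analytic species
#'
#' Explicit probability vector on the product lattice
#' `0..nmax[1] x ... x 0..nmax[s]` of the G2 species of a network, stored
#' in column-major order (first species fastest).
#'
#' @param network A `reaction_network`.
#' @param lambda Poisson mean per G2 species; the constructor builds the
#'   product-Poisson distribution truncated to the lattice.
#' @param nmax Lattice bound per G2 species; defaults to
#'   `ceiling(mean + 10*sqrt(mean) + 20)` per species.
#' @return Object of class `truncated_distribution`: fields `p`, `nmax`,
#'   `species`.
#' @export
truncated_poisson <- function(network, lambda, nmax = NULL) {
  g2 <- network$species$name[network$species$group == "G2"]
  stopifnot(length(lambda) == length(g2), all(lambda >= 0))
  if (is.null(nmax)) nmax <- oracle_nmax(lambda)
  stopifnot(length(nmax) == length(g2))
  marg <- lapply(seq_along(g2), function(i) dpois(0:nmax[i], lambda[i]))
  p <- Reduce(function(x, y) as.vector(outer(x, y)), marg)
  new_truncated(p, nmax, g2)
}

new_truncated <- function(p, nmax, species) {
  structure(list(p = p, nmax = as.integer(nmax), species = species),
            class = "truncated_distribution")
}

#' @rdname truncated_poisson
#' @param mean Expected copy number(s).
#' @export
oracle_nmax <- function(mean) {
  pmax(10L, as.integer(ceiling(mean + 10 * sqrt(mean) + 20)))
}

#' @exportS3Method base::print
print.truncated_distribution <- function(x, ...) {
  cat("<truncated_distribution>", paste(x$species, collapse = ", "),
      "| nmax:", paste(x$nmax, collapse = ", "),
      "| total mass:", format(sum(x$p), digits = 12), "\n")
  invisible(x)
}

## lattice states as a data frame of G2 counts (first species fastest)
lattice_states <- function(nmax, species) {
  g <- do.call(expand.grid, lapply(nmax, function(n) 0:n))
  names(g) <- species
  g
}

## vectorized mass-action propensities over lattice states, G1 species
## fixed at g1_state
propensity_lattice <- function(network, g1_state, states, group) {
  rx <- Filter(function(r) r$group == group, network$reactions)
  fixed <- setNames(numeric(nrow(network$species)), network$species$name)
  fixed[names(g1_state)] <- g1_state
  out <- matrix(0, nrow(states), length(rx))
  colnames(out) <- vapply(rx, `[[`, character(1), "name")
  for (j in seq_along(rx)) {
    a <- numeric(nrow(states))
    for (tm in rx[[j]]$terms) {
      v <- rep(tm$coef, nrow(states))
      for (s in tm$species) {
        v <- v * if (s %in% names(states)) states[[s]] else fixed[[s]]
      }
      a <- a + v
    }
    out[, j] <- a
  }
  out
}

## sparse generator of the G2-only master equation at fixed G1 state.
## Transitions that would leave the lattice are suppressed entirely
## (reflecting boundary): truncation error then accumulates as visible
## boundary mass, which the adaptivity check catches, instead of leaking
## away silently.
g2_generator <- function(network, g1_state, nmax) {
  g2 <- network$species$name[network$species$group == "G2"]
  states <- lattice_states(nmax, g2)
  ns <- nrow(states)
  a <- propensity_lattice(network, g1_state, states, "G2")
  rx <- Filter(function(r) r$group == "G2", network$reactions)
  stride <- cumprod(c(1, nmax[-length(nmax)] + 1))
  idx0 <- as.matrix(states) %*% stride # 0-based linear index
  trip_i <- trip_j <- integer(0)
  trip_x <- numeric(0)
  for (j in seq_along(rx)) {
    v <- rx[[j]]$stoich[g2]
    tgt <- sweep(as.matrix(states), 2, v, "+")
    ok <- rowSums(tgt < 0) == 0 & rowSums(sweep(tgt, 2, nmax, ">")) == 0
    ti <- as.vector(tgt %*% stride)[ok] + 1L
    fj <- which(ok)
    trip_i <- c(trip_i, ti, fj)
    trip_j <- c(trip_j, fj, fj)
    trip_x <- c(trip_x, a[ok, j], -a[ok, j])
  }
  A <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(ns, ns))
  list(A = A, states = states, idx0 = idx0)
}

oracle_ode <- function(A, p0, t, rtol, atol) {
  f <- function(tt, y, parms) list(as.vector(A %*% y))
  out <- deSolve::ode(y = p0, times = c(0, t), func = f, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 1e6)
  out[nrow(out), -1]
}

boundary_mass <- function(p, states, nmax) {
  onb <- rowSums(sweep(as.matrix(states), 2, nmax, "==")) > 0
  sum(p[onb])
}

#' Integrate the analytic sub-network's master equation
#'
#' Numerically solves the G2-only master equation at fixed simulated state
#' (`integrate_P`), or its unnormalized variant whose loss term carries
#' all propensities -- simulated and analytic -- and whose total mass is
#' the survival probability of the simulated group (`integrate_Q`).
#' The lattice is enlarged and the integration restarted whenever more
#' than 1e-12 of the mass reaches the boundary.
#'
#' @param network A `reaction_network`.
#' @param g1_state Named vector fixing the G1 species (one-hot promoter
#'   indicators and `m`).
#' @param p0 A `truncated_distribution` (e.g. [truncated_poisson()]).
#' @param t Time to integrate to (minutes).
#' @param rtol,atol Integrator tolerances.
#' @return `integrate_P`: a `truncated_distribution` at time `t`.
#'   `integrate_Q`: list with the unnormalized `dist` and the scalar
#'   `survival`.
#' @export
integrate_P <- function(network, g1_state, p0, t, rtol = 1e-11,
                        atol = 1e-13) {
  oracle_integrate(network, g1_state, p0, t, g1_loss = FALSE, rtol, atol)
}

#' @rdname integrate_P
#' @export
integrate_Q <- function(network, g1_state, p0, t, rtol = 1e-11,
                        atol = 1e-13) {
  res <- oracle_integrate(network, g1_state, p0, t, g1_loss = TRUE, rtol,
                          atol)
  list(dist = res, survival = sum(res$p))
}

oracle_integrate <- function(network, g1_state, p0, t, g1_loss, rtol,
                             atol) {
  stopifnot(inherits(p0, "truncated_distribution"), t >= 0)
  if (t == 0) return(p0)
  nmax <- p0$nmax
  p <- p0$p
  for (attempt in 1:6) {
    gen <- g2_generator(network, g1_state, nmax)
    A <- gen$A
    if (g1_loss) {
      a1 <- propensity_lattice(network, g1_state, gen$states, "G1")
      A <- A - Matrix::Diagonal(x = rowSums(a1))
    }
    res <- oracle_ode(A, p, t, rtol, atol)
    if (boundary_mass(res, gen$states, nmax) < 1e-12) {
      return(new_truncated(as.numeric(res), nmax, p0$species))
    }
    ## enlarge and pad
    nm2 <- as.integer(ceiling(nmax * 1.5) + 5L)
    big <- array(0, nm2 + 1L)
    old <- array(p, nmax + 1L)
    idx <- lapply(nmax, function(n) seq_len(n + 1L))
    big[do.call(cbind, expand.grid(idx))] <- old
    ## (assignment via index matrix keeps arbitrary dimension count)
    p <- as.vector(big)
    nmax <- nm2
  }
  stop("lattice enlargement did not contain the boundary mass")
}

#' Brute-force marginalized reaction probabilities
#'
#' Direct lattice summation of the next-reaction probabilities of the
#' simulated group: `p_mu = sum_n P(n) a_mu(n) / a(n)` with `a` the summed
#' G1 propensity. The independent check for the closed-form
#' marginalizations.
#'
#' @inheritParams integrate_P
#' @param p A normalized `truncated_distribution`.
#' @return Probability vector over the G1 reactions (model channel order).
#' @export
marginal_reaction_probs <- function(network, g1_state, p) {
  stopifnot(inherits(p, "truncated_distribution"))
  g2 <- network$species$name[network$species$group == "G2"]
  states <- lattice_states(p$nmax, g2)
  a1 <- propensity_lattice(network, g1_state, states, "G1")
  tot <- rowSums(a1)
  w <- ifelse(tot > 0, p$p / ifelse(tot > 0, tot, 1), 0)
  as.numeric(colSums(a1 * w))
}

#' Mean copy numbers of a truncated distribution
#'
#' @param p A `truncated_distribution`.
#' @return Named numeric vector of per-species means.
#' @export
lattice_mean <- function(p) {
  states <- lattice_states(p$nmax, p$species)
  setNames(as.numeric(colSums(states * p$p)), p$species)
}
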