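#' Exponential waiting time of the direct method
#'
#' Inverts the waiting-time CDF: `tau = (1/a0) * ln(1/r1)`.
#'
#' @param a0 Total propensity (per minute), must be positive; `a0 = 0`
#'   signals an absorbing state and is rejected here (the simulators hold
#'   the state to the final time instead).
#' @param r1 Uniform variate in (0, 1].
#' @return Waiting time in minutes.
#' @export
draw_waiting_time <- function(a0, r1) {
  stopifnot(r1 > 0, r1 <= 1)
  if (a0 <= 0) stop("absorbing state: total propensity is zero",
                    call. = FALSE)
  log(1 / r1) / a0
}

#' Direct-method reaction selection
#'
#' Smallest index `j` whose cumulative propensity exceeds `r2 * a0`.
#'
#' @param propensities Non-negative numeric vector with positive sum.
#' @param r2 Uniform variate in [0, 1).
#' @return The 1-based reaction index.
#' @export
select_reaction <- function(propensities, r2) {
  stopifnot(all(propensities >= 0), r2 >= 0, r2 < 1)
  a0 <- sum(propensities)
  if (a0 <= 0) stop("all propensities zero: absorbing state", call. = FALSE)
  which(cumsum(propensities) > r2 * a0)[1L]
}

## Flatten a reaction_network for the compiled cores.  Terms are capped at
## two species factors, which covers every mass-action reaction used here.
encode_network <- function(network) {
  sp <- network$species$name
  nrx <- length(network$reactions)
  stoich <- matrix(0L, nrx, length(sp))
  coef <- numeric(0); trx <- integer(0)
  tsp1 <- integer(0); tsp2 <- integer(0)
  group <- integer(nrx)
  for (i in seq_len(nrx)) {
    r <- network$reactions[[i]]
    stoich[i, ] <- r$stoich[sp]
    group[i] <- if (r$group == "G1") 1L else 2L
    for (tm in r$terms) {
      if (length(tm$species) > 2L) {
        stop("mass-action terms with more than two factors are not supported")
      }
      coef <- c(coef, tm$coef)
      trx <- c(trx, i - 1L)
      idx <- match(tm$species, sp) - 1L
      tsp1 <- c(tsp1, if (length(idx) >= 1L) idx[1L] else -1L)
      tsp2 <- c(tsp2, if (length(idx) >= 2L) idx[2L] else -1L)
    }
  }
  list(nsp = length(sp), stoich = stoich, coef = coef, trx = trx,
       tsp1 = tsp1, tsp2 = tsp2, group = group)
}

#' Exact stochastic simulation of the full network
#'
#' Direct-method realization(s) of a `reaction_network`, recorded on a
#' uniform (or any sorted) time grid by zero-order hold: the value at a
#' grid point is the state after the last event at or before it.
#'
#' @param network A `reaction_network`.
#' @param init Named initial state (defaults to [default_init()]).
#' @param t_final Final time, minutes.
#' @param seed Integer root seed. Realization `i` uses an independently
#'   derived child stream, so ensembles are reproducible and
#'   order-independent.
#' @param record_times Sorted numeric vector of recording times in
#'   `[0, t_final]`; defaults to 101 uniform points.
#' @param n_real Number of realizations.
#' @param stream_offset Offset added to the child-stream index (lets two
#'   ensembles share a root seed without sharing randomness).
#' @return An array `[time, species, realization]` with dimnames, classed
#'   `ensemble_states`; `attr(, "times")` holds the grid.
#' @examples
#' net <- switch_network()
#' x <- simulate_ssa(net, t_final = 10, seed = 1,
#'                   record_times = seq(0, 10, 1))
#' x[, "m", 1]
#' @export
simulate_ssa <- function(network, init = default_init(network), t_final,
                         seed, record_times = seq(0, t_final, length.out = 101),
                         n_real = 1, stream_offset = 0) {
  stopifnot(t_final > 0, !is.unsorted(record_times),
            all(record_times >= 0), all(record_times <= t_final))
  validate_network(network, init[network$species$name])
  enc <- encode_network(network)
  out <- .ssa_ensemble_cpp(enc, as.numeric(init[network$species$name]),
                           t_final, as.numeric(record_times), seed,
                           as.integer(n_real), as.integer(stream_offset))
  dimnames(out) <- list(NULL, network$species$name, NULL)
  structure(out, times = as.numeric(record_times), model = network$model,
            seed = seed, class = "ensemble_states")
}

#' First simulated-group event times of the full SSA
#'
#' Runs the full network and reports the time of the first group-G1
#' reaction of each realization; used to validate the closed-form survival
#' function. The initial count of one species can be drawn from a Poisson
#' distribution per realization.
#'
#' @inheritParams simulate_ssa
#' @param t_cap Censoring horizon; censored realizations report
#'   `t_cap + 1`.
#' @param poisson_species Optional species name whose initial count is
#'   drawn from Poisson(`poisson_mean`).
#' @param poisson_mean Mean for `poisson_species`.
#' @return Numeric vector of first-event times.
#' @export
ssa_first_g1 <- function(network, init = default_init(network), t_cap, seed,
                         n_real, poisson_species = NULL, poisson_mean = 0) {
  enc <- encode_network(network)
  ps <- if (is.null(poisson_species)) -1L else {
    match(poisson_species, network$species$name) - 1L
  }
  .ssa_first_g1_cpp(enc, as.numeric(init[network$species$name]), t_cap,
                    seed, as.integer(n_real), as.integer(ps), poisson_mean)
}

#' @exportS3Method base::print
print.ensemble_states <- function(x, ...) {
  d <- dim(x)
  cat("<ensemble_states>", d[3], "realization(s) x", d[1], "times x",
      d[2], "variables (", paste(dimnames(x)[[2]], collapse = ", "), ")\n")
  invisible(x)
}
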