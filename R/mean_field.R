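#' Mean-field right-hand side
#'
#' Time derivative of the averaged variables of a built-in model. For the
#' switch the state is `(S1, S2, m, n)`; for the Griffith model it is
#' `(S1, S2, S3, S4, m, n1, ..., nd)`. In both cases the empty-promoter
#' fraction is eliminated by the conservation closure
#' `S0 = 1 - sum(other indicators)`, so the indicator fractions sum to one by
#' construction. Note that for the switch the basal transcription term `r0`
#' enters the mean-field mRNA equation independently of promoter occupancy,
#' while the stochastic network groups it with the occupancy-weighted
#' channel; the two conventions are each kept verbatim.
#'
#' @param network A `reaction_network`.
#' @param state Named numeric vector (see above).
#' @param t Time (unused; the system is autonomous).
#' @return Named numeric vector of derivatives.
#' @export
mean_field_rhs <- function(network, state, t = 0) {
  p <- network$params
  if (network$model == "switch") {
    S1 <- state[["S1"]]; S2 <- state[["S2"]]
    m <- state[["m"]]; n <- state[["n"]]
    S0 <- 1 - S1 - S2
    c(S1 = p$alpha1 * n * S0 + p$beta2 * S2 -
        (p$alpha2 * S1 * n + p$beta1) * S1,
      S2 = p$alpha2 * S1 * n - p$beta2 * S2,
      m = p$r * S2 + p$r0 - p$k * m,
      n = p$K * m - p$q * n)
  } else {
    d <- network$d
    S <- unlist(state[paste0("S", 1:4)])
    m <- state[["m"]]
    n <- unlist(state[paste0("n", seq_len(d))])
    S0 <- 1 - sum(S)
    al <- unlist(p[paste0("alpha", 1:4)])
    be <- unlist(p[paste0("beta", 1:4)])
    nd <- n[d]
    dS <- c(al[1] * nd * S0 + be[2] * S[2] - (al[2] * nd + be[1]) * S[1],
            al[2] * nd * S[1] + be[3] * S[3] - (al[3] * nd + be[2]) * S[2],
            al[3] * nd * S[2] + be[4] * S[4] - (al[4] * nd + be[3]) * S[3],
            al[4] * nd * S[3] - be[4] * S[4])
    dn <- c(p$K * m - p$a * n[1],
            if (d > 2) p$a * (n[seq_len(d - 2)] - n[1 + seq_len(d - 2)]),
            p$a * n[d - 1] - p$q * n[d])
    setNames(c(dS, p$r * S0 - p$k * m, dn),
             c(paste0("S", 1:4), "m", paste0("n", seq_len(d))))
  }
}

#' Integrate the mean-field equations
#'
#' @param network A `reaction_network`.
#' @param times Numeric vector of output times (minutes), starting at the
#'   initial time.
#' @param init Optional named initial state for [mean_field_rhs()]; default
#'   is the empty promoter with no mRNA or protein.
#' @param ... Passed to [deSolve::ode()] (e.g. `rtol`, `atol`).
#' @return A matrix with a `time` column, the mean-field variables, and the
#'   reconstructed `S0` column.
#' @export
solve_mean_field <- function(network, times, init = NULL, ...) {
  if (is.null(init)) {
    init <- if (network$model == "switch") {
      c(S1 = 0, S2 = 0, m = 0, n = 0)
    } else {
      setNames(numeric(5 + network$d),
               c(paste0("S", 1:4), "m", paste0("n", seq_len(network$d))))
    }
  }
  rhs <- function(t, y, parms) list(mean_field_rhs(network, y, t))
  out <- deSolve::ode(y = init, times = times, func = rhs, parms = NULL, ...)
  ind <- if (network$model == "switch") c("S1", "S2") else paste0("S", 1:4)
  cbind(as.matrix(out), S0 = 1 - rowSums(out[, ind, drop = FALSE]))
}
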