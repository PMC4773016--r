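## Independent oracles used across the suite.  Everything here is built
## from base R / deSolve primitives, never from the package's closed forms.

## brute-force Poisson inverse moment by fixed-length partial summation
brute_inverse_moment <- function(a, lambda, nterms = 200) {
  if (lambda == 0) return(1 / a)
  n <- 0:(nterms - 1)
  sum(exp(-lambda + n * log(lambda) - lfactorial(n) - log(n + a)))
}

## brute-force marginalized next-reaction probabilities: truncated Poisson
## sum over the single analytic species entering the simulated propensities
brute_reaction_probs <- function(network, g1_state, lambda,
                                 nmax = ceiling(lambda + 12 * sqrt(lambda) +
                                                  60)) {
  free <- if (network$model == "switch") "n" else paste0("n", network$d)
  full <- setNames(numeric(nrow(network$species)), network$species$name)
  full[names(g1_state)] <- g1_state
  nrx <- sum(vapply(network$reactions, function(r) r$group == "G1",
                    logical(1)))
  acc <- numeric(nrx)
  for (n in 0:nmax) {
    full[free] <- n
    a <- propensities(network, full, group = "G1")
    tot <- sum(a)
    if (tot > 0) acc <- acc + dpois(n, lambda) * a / tot
  }
  acc
}

## one-hot G1 state vectors
switch_g1 <- function(promoter, m) {
  c(setNames(as.numeric(0:2 == promoter), paste0("S", 0:2)), m = m)
}
griffith_g1 <- function(promoter, m) {
  c(setNames(as.numeric(0:4 == promoter), paste0("S", 0:4)), m = m)
}

## deSolve integration of the switch survival auxiliaries (the oracle for
## the closed forms of lambda, h, g)
ode_switch_lhg <- function(t_out, lambda0, Km, q, q_tilde, K_tilde) {
  rhs <- function(t, y, p) {
    list(c(Km - q * y[1],              # lambda
          Km - q_tilde * y[2],         # h
          K_tilde - q * y[2]))         # g
  }
  out <- deSolve::ode(c(lambda0, lambda0, lambda0), t_out, rhs, NULL,
                      rtol = 1e-12, atol = 1e-12)
  list(lambda = out[, 2], h = out[, 3], g = out[, 4])
}

## deSolve integration of the conversion cascade means
ode_cascade <- function(t_out, lambda0, Km, a, qlast) {
  d <- length(lambda0)
  rhs <- function(t, y, p) {
    dy <- numeric(d)
    dy[1] <- Km - a * y[1]
    if (d > 2) for (i in 2:(d - 1)) dy[i] <- a * (y[i - 1] - y[i])
    dy[d] <- a * y[d - 1] - qlast * y[d]
    list(dy)
  }
  deSolve::ode(lambda0, t_out, rhs, NULL, rtol = 1e-12, atol = 1e-12)[, -1,
                                                                     drop = FALSE]
}

## delta/arbitrary truncated distributions (internal constructor)
new_truncated_for_test <- function(p, nmax, species) {
  hybridCME:::new_truncated(p, nmax, species)
}
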