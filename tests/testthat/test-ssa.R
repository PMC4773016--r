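test_that("waiting-time inversion has the exponential closed form", {
  expect_equal(draw_waiting_time(2, 1), 0)
  expect_equal(draw_waiting_time(2, exp(-2)), 1)
  expect_error(draw_waiting_time(0, 0.5), "absorbing")
  ## distributional check: 1e5 inverted uniforms against Exponential(a0)
  set.seed(101)
  a0 <- 0.7
  tau <- vapply(runif(1e5), function(u) draw_waiting_time(a0, u),
                numeric(1))
  ks <- suppressWarnings(ks.test(tau, pexp, rate = a0))
  expect_gt(ks$p.value, 0.001)
})

test_that("reaction selection picks the smallest cumulative index", {
  expect_equal(select_reaction(c(1, 0, 0), 0.99), 1)
  expect_equal(select_reaction(c(1, 3), 0.2), 1) # cumulative (1,4); 1 > 0.8
  expect_equal(select_reaction(c(1, 3), 0.3), 2)
  expect_error(select_reaction(c(0, 0), 0.1), "absorbing")
  ## sampled frequencies match a_mu / a0 within 3 sigma (multinomial)
  set.seed(102)
  a <- c(0.5, 2.5, 1)
  draws <- vapply(runif(1e5), function(u) select_reaction(a, u),
                  numeric(1))
  p <- a / sum(a)
  for (j in 1:3) {
    phat <- mean(draws == j)
    expect_lt(abs(phat - p[j]), 3 * sqrt(p[j] * (1 - p[j]) / 1e5))
  }
})

test_that("pure-decay ensemble mean follows the exponential solution", {
  ## single-reaction death process embedded in the switch network is not
  ## available, so build the comparison from the full network with only
  ## protein decay active: S2 occupied, no mRNA, large initial n
  net <- switch_network(switch_params(alpha1 = 1e-12, alpha2 = 1e-12,
                                      beta1 = 1e-12, beta2 = 1e-12,
                                      r0 = 1e-12, r = 1e-12, K = 1e-12,
                                      k = 1e-12))
  N0 <- 60
  init <- c(S0 = 1, S1 = 0, S2 = 0, m = 0, n = N0)
  grid <- seq(0, 100, 10)
  x <- simulate_ssa(net, init, t_final = 100, seed = 7,
                    record_times = grid, n_real = 2000)
  q <- net$params$q
  mean_n <- apply(x[, "n", ], 1, mean)
  se_n <- apply(x[, "n", ], 1, sd) / sqrt(2000)
  expected <- N0 * exp(-q * grid)
  expect_true(all(abs(mean_n - expected) <= 3 * pmax(se_n, 1e-9) + 1e-9))
})

test_that("trajectories are reproducible and respect absorbing states", {
  net <- switch_network()
  a <- simulate_ssa(net, t_final = 30, seed = 9,
                    record_times = seq(0, 30, 1))
  b <- simulate_ssa(net, t_final = 30, seed = 9,
                    record_times = seq(0, 30, 1))
  expect_identical(unclass(a), unclass(b))
  c2 <- simulate_ssa(net, t_final = 30, seed = 10,
                     record_times = seq(0, 30, 1))
  expect_false(identical(unclass(a), unclass(c2)))
  ## absorbing: all rates effectively zero and empty state -> held forever
  net0 <- switch_network(switch_params(alpha1 = 1e-300, alpha2 = 1e-300,
                                       beta1 = 1e-300, beta2 = 1e-300,
                                       r0 = 1e-300, r = 1e-300, K = 1e-300,
                                       k = 1e-300, q = 1e-300))
  x <- simulate_ssa(net0, t_final = 10, seed = 1,
                    record_times = seq(0, 10, 1))
  expect_true(all(x[, "m", 1] == 0) && all(x[, "n", 1] == 0))
})

test_that("two-state birth-death occupancy matches the Poisson law", {
  ## translation/decay at fixed m = 1: stationary n ~ Poisson(K/q); run one
  ## long trajectory of the G2 subsystem via the full network with locked
  ## promoter and mRNA (binding/transcription/decay rates driven to zero)
  p <- switch_params(alpha1 = 1e-300, alpha2 = 1e-300, beta1 = 1e-300,
                     beta2 = 1e-300, r0 = 1e-300, r = 1e-300, k = 1e-300,
                     K = 2, q = 0.5)
  net <- switch_network(p)
  init <- c(S0 = 1, S1 = 0, S2 = 0, m = 1, n = 0)
  grid <- seq(200, 2200, 0.5) # decorrelated samples after burn-in
  x <- simulate_ssa(net, init, t_final = 2200, seed = 3,
                    record_times = grid)
  n <- x[, "n", 1]
  lam <- p$K / p$q
  expect_lt(abs(mean(n) - lam) / lam, 0.05)
  expect_lt(abs(var(n) - lam) / lam, 0.15)
})
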