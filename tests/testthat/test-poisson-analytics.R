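test_that("effective switch rates keep only the occupied-state terms", {
  p <- switch_params()
  er <- effective_rates_switch(switch_g1(0, 0), p)
  expect_equal(er$q_tilde, p$alpha1 + p$q)
  expect_equal(er$K_tilde, p$r0)
  er <- effective_rates_switch(switch_g1(2, 3), p)
  expect_equal(er$q_tilde, p$q)
  expect_equal(er$K_tilde, p$beta2 + p$r + (p$K + p$k) * 3)
})

test_that("switch mean/survival solutions match direct integration", {
  p <- switch_params()
  ## lambda: fixed point and generic state against the ODE oracle
  expect_equal(lambda_switch(0, 7, p$K, 2, p$q), 7)
  lam_fix <- p$K * 2 / p$q
  expect_equal(lambda_switch(c(5, 50), lam_fix, p$K, 2, p$q),
               rep(lam_fix, 2))
  st <- switch_g1(0, 2)
  er <- effective_rates_switch(st, p)
  tt <- c(0, 1, 10, 100)
  ode <- ode_switch_lhg(tt, 0, p$K * 2, p$q, er$q_tilde, er$K_tilde)
  expect_equal(lambda_switch(tt, 0, p$K, 2, p$q), unname(ode$lambda),
               tolerance = 1e-8)
  hg <- h_g_switch(tt, 0, st, p)
  expect_equal(hg$h, unname(ode$h), tolerance = 1e-8)
  expect_equal(hg$g, unname(ode$g), tolerance = 1e-8)
  ## t = 0 resets
  hg0 <- h_g_switch(0, 12, st, p)
  expect_equal(c(hg0$h, hg0$g), c(12, 12))
})

test_that("switch survival is 1 at 0, monotone, and trivial when G1 silent", {
  st <- switch_g1(1, 1)
  tau <- seq(0, 8, 0.25)
  q <- survival_switch(tau, 20, st)
  expect_equal(q[1], 1)
  expect_true(all(diff(q) < 0))
  ## log-concave while the pool grows toward its effective fixed point
  lq <- log_survival_switch(tau, 20, st)
  expect_true(all(diff(diff(lq)) < 1e-12))
  ## all G1 propensities zero forces Q == 1: q_tilde = q and K_tilde = K m
  p0 <- switch_params(alpha1 = 1e-300, alpha2 = 1e-300, beta1 = 1e-300,
                      beta2 = 1e-300, r0 = 1e-300, r = 1e-300, k = 1e-300)
  q1 <- survival_switch(tau, 20, switch_g1(0, 3), p0)
  expect_equal(q1, rep(1, length(tau)), tolerance = 1e-10)
})

test_that("cascade means match direct integration, including a = q", {
  p <- griffith_params()
  lam0 <- c(2, 7, 1)
  expect_equal(lambda_griffith(0, lam0, p$K, 5, p$a, p$q), lam0)
  tt <- seq(0, 50, 5)
  ode <- ode_cascade(tt, lam0, p$K * 5, p$a, p$q)
  cf <- lambda_griffith(tt, lam0, p$K, 5, p$a, p$q)
  expect_lt(max(abs(ode - cf)), 1e-7)
  ## long-time limits: Km/a for the pre-terminal stages, Km/q terminal
  lim <- lambda_griffith(4000, lam0, p$K, 5, p$a, p$q)
  expect_equal(lim, c(rep(p$K * 5 / p$a, 2), p$K * 5 / p$q),
               tolerance = 1e-6)
  ## confluent case a = q via the analytic limit
  ode2 <- ode_cascade(tt, lam0, p$K * 5, 0.1, 0.1)
  cf2 <- lambda_griffith(tt, lam0, p$K, 5, 0.1, 0.1)
  expect_lt(max(abs(ode2 - cf2)), 1e-7)
  ## near-confluent case brackets the limit continuously
  cf3 <- lambda_griffith(tt, lam0, p$K, 5, 0.1, 0.1 + 1e-9)
  expect_lt(max(abs(cf3 - cf2)), 1e-5)
})

test_that("griffith g(t) integrates K_tilde - q h_d with Q(0) = 1", {
  p <- griffith_params()
  st <- griffith_g1(1, 2)
  lam0 <- c(3, 1, 6)
  er <- effective_rates_griffith(st, p)
  expect_equal(g_griffith(0, lam0, st, p), sum(lam0)) # normalization
  expect_equal(survival_griffith(0, lam0, st, p), 1)
  ## dg/dt by central differences equals K_tilde - q h_d
  tt <- c(0.5, 2, 5, 9)
  hmat <- h_griffith(tt, lam0, st, p, drop = FALSE)
  eps <- 1e-5
  dg <- (g_griffith(tt + eps, lam0, st, p) -
           g_griffith(tt - eps, lam0, st, p)) / (2 * eps)
  expect_lt(max(abs(dg - (er$K_tilde - p$q * hmat[, 3]))), 1e-6)
  ## survival monotone
  qs <- survival_griffith(seq(0, 5, 0.2), lam0, st, p)
  expect_true(all(diff(qs) < 0))
})

test_that("inverse moment series agrees with identities and brute force", {
  expect_equal(poisson_inverse_moment(3.7, 0), 1 / 3.7)
  lam <- c(0.3, 2, 17)
  expect_equal(poisson_inverse_moment(1, lam), (1 - exp(-lam)) / lam,
               tolerance = 1e-13)
  expect_equal(poisson_inverse_moment(2.5, 3),
               brute_inverse_moment(2.5, 3), tolerance = 1e-13)
  expect_error(poisson_inverse_moment(0, 1), "a must be")
  expect_error(poisson_inverse_moment(-2, 1), "a must be")
  ## large-mean branch (windowed summation) against a direct dpois sum
  v <- poisson_inverse_moment(10, 900)
  ref <- sum(dpois(500:1300, 900) / (500:1300 + 10))
  expect_equal(v, ref, tolerance = 1e-12)
})

test_that("three-term approximation is sharp for large arguments only", {
  expect_equal(approx_inverse_moment(5, 0), 1 / 5)
  e1 <- poisson_inverse_moment(100, 50)
  expect_lt(abs(approx_inverse_moment(100, 50) - e1) / e1, 1e-4)
  ## the documented caution: small lambda and a degrade the expansion
  e2 <- poisson_inverse_moment(0.5, 0.5)
  rel_small <- abs(approx_inverse_moment(0.5, 0.5) - e2) / e2
  rel_large <- abs(approx_inverse_moment(100, 50) - e1) / e1
  expect_gt(rel_small, 100 * rel_large)
})

test_that("fast waiting-time path obeys its quadratic error control", {
  ## b2 = 0: the expansion is exact
  ft <- fast_tau(0.37, 2, 0)
  expect_true(ft$fast_ok)
  expect_equal(ft$tau0, log(1 / 0.37) / 2)
  ## xi1 -> 1: tau -> 0 and the fast path always accepts
  ft <- fast_tau(1 - 1e-12, 1, 5)
  expect_true(ft$fast_ok)
  expect_lt(ft$tau0, 1e-11)
  ## documented example: accepted root stays within eps of the quadratic
  ft <- fast_tau(0.5, 1, 0.1, eps = 0.05)
  expect_true(ft$fast_ok)
  tq <- uniroot(function(u) -u + 0.05 * u^2 - log(0.5), c(0, 10),
                tol = 1e-14)$root
  expect_lt(abs(ft$tau0 - tq) / tq, 0.05)
  ## b1 <= 0 forces the fallback
  expect_false(fast_tau(0.5, 0, 1)$fast_ok)
})

test_that("b1 equals the simulated propensity sum at n = lambda(0)", {
  net <- switch_network()
  p <- net$params
  for (pr in 0:2) {
    lam0 <- 37.2
    m <- 3
    st <- switch_g1(pr, m)
    er <- effective_rates_switch(st, p)
    b1 <- er$K_tilde - p$K * m + (er$q_tilde - p$q) * lam0
    full <- c(st, n = lam0)
    expect_equal(b1, sum(propensities(net, full, group = "G1")),
                 tolerance = 1e-12)
  }
  gnet <- griffith_network(d = 4)
  gp <- gnet$params
  for (pr in 0:4) {
    lam0 <- c(1, 2, 3, 41.5)
    st <- griffith_g1(pr, 2)
    er <- effective_rates_griffith(st, gp)
    b1 <- er$K_tilde - gp$K * 2 + (er$q_tilde - gp$q) * lam0[4]
    full <- setNames(numeric(nrow(gnet$species)), gnet$species$name)
    full[names(st)] <- st
    full["n4"] <- lam0[4]
    expect_equal(b1, sum(propensities(gnet, full, group = "G1")),
                 tolerance = 1e-12)
  }
})
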