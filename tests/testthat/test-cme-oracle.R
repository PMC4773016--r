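test_that("lattice integration conserves mass and honors trivial cases", {
  net <- switch_network()
  g1 <- switch_g1(0, 1)
  p0 <- truncated_poisson(net, 10)
  expect_equal(sum(p0$p), 1, tolerance = 1e-10)
  ## t = 0 returns the initial distribution
  expect_equal(integrate_P(net, g1, p0, 0)$p, p0$p)
  pt <- integrate_P(net, g1, p0, 5)
  expect_equal(sum(pt$p), 1, tolerance = 1e-9)
  expect_true(all(pt$p > -1e-12))
})

test_that("without production the lattice mean decays exponentially", {
  net <- switch_network()
  g1 <- switch_g1(0, 0) # m = 0: no translation
  p0 <- truncated_poisson(net, 15)
  pt <- integrate_P(net, g1, p0, 30)
  expect_equal(unname(lattice_mean(pt)), 15 * exp(-net$params$q * 30),
               tolerance = 1e-7)
})

test_that("Poisson in, Poisson out: the ansatz honored to truncation error", {
  net <- switch_network()
  g1 <- switch_g1(1, 2)
  lam0 <- 8
  p0 <- truncated_poisson(net, lam0, oracle_nmax(60))
  for (t in c(1, 10)) {
    pt <- integrate_P(net, g1, p0, t)
    lam_t <- lambda_switch(t, lam0, net$params$K, 2, net$params$q)
    tv <- 0.5 * sum(abs(pt$p - dpois(0:pt$nmax, lam_t)))
    expect_lt(tv, 1e-8)
  }
})

test_that("unnormalized solution reproduces the closed-form survival", {
  net <- switch_network()
  g1 <- switch_g1(0, 1)
  p0 <- truncated_poisson(net, 10, oracle_nmax(110))
  expect_equal(integrate_Q(net, g1, p0, 0)$survival, 1, tolerance = 1e-10)
  for (tau in c(0.5, 2, 5)) {
    qres <- integrate_Q(net, g1, p0, tau)
    expect_equal(qres$survival, survival_switch(tau, 10, g1),
                 tolerance = 1e-8)
  }
  ## with G1 silenced the unnormalized equation reduces to the normalized
  ## one: survival identically 1
  p_off <- switch_params(alpha1 = 1e-300, alpha2 = 1e-300, beta1 = 1e-300,
                         beta2 = 1e-300, r0 = 1e-300, r = 1e-300,
                         k = 1e-300)
  net0 <- switch_network(p_off)
  q0 <- integrate_Q(net0, switch_g1(0, 2), truncated_poisson(net0, 10), 3)
  expect_equal(q0$survival, 1, tolerance = 1e-8)
  pnorm <- integrate_P(net0, switch_g1(0, 2), truncated_poisson(net0, 10),
                       3)
  expect_equal(q0$dist$p, pnorm$p, tolerance = 1e-9)
})

test_that("griffith product-Poisson ansatz verified on the joint lattice", {
  net <- griffith_network(d = 2)
  g1 <- griffith_g1(0, 2)
  lam0 <- c(3, 4)
  p0 <- truncated_poisson(net, lam0)
  pt <- integrate_P(net, g1, p0, 4)
  lam_t <- lambda_griffith(4, lam0, net$params$K, 2, net$params$a,
                           net$params$q)
  expected <- truncated_poisson(net, lam_t, pt$nmax)
  expect_lt(0.5 * sum(abs(pt$p - expected$p)), 1e-8)
  ## survival of the unnormalized twin matches the closed form; use a
  ## state with moderate decay (occupied promoter, no mRNA) so that the
  ## comparison is well conditioned, and compare on the log scale
  g1s <- griffith_g1(1, 0)
  p0s <- truncated_poisson(net, lam0)
  for (tau in c(0.5, 1.5, 4)) {
    qres <- integrate_Q(net, g1s, p0s, tau)
    expect_equal(log(qres$survival),
                 log(survival_griffith(tau, lam0, g1s, net$params)),
                 tolerance = 1e-7)
  }
  ## the variant without +q in the effective decay does NOT satisfy the
  ## master equation (this is what pins down the default)
  s_var <- survival_griffith(4, lam0, g1s, net$params,
                             qtilde_printed = TRUE)
  expect_gt(abs(log(integrate_Q(net, g1s, p0s, 4)$survival) - log(s_var)),
            1e-3)
})

test_that("marginalized probabilities reduce to Gillespie weights on deltas", {
  net <- switch_network()
  g1 <- switch_g1(0, 2)
  ## delta distribution at n = 12
  nmax <- 40
  p <- new_truncated_for_test(c(rep(0, 12), 1, rep(0, nmax - 12)), nmax,
                              "n")
  pr <- marginal_reaction_probs(net, g1, p)
  full <- c(g1, n = 12)
  a <- propensities(net, full, group = "G1")
  expect_equal(pr, unname(a / sum(a)), tolerance = 1e-12)
})

test_that("oracle first moments follow the hidden-mean equations", {
  ## switch: d<n>/dt = K m - q <n> at fixed G1 state
  net <- switch_network()
  g1 <- switch_g1(2, 3)
  p0 <- truncated_poisson(net, 5, oracle_nmax(350))
  tt <- 20
  pt <- integrate_P(net, g1, p0, tt)
  ode <- deSolve::ode(c(n = 5), c(0, tt), function(t, y, p) {
    list(net$params$K * 3 - net$params$q * y)
  }, NULL, rtol = 1e-12, atol = 1e-12)
  expect_equal(unname(lattice_mean(pt)), unname(ode[2, 2]),
               tolerance = 1e-8)
  ## griffith d = 2: the conversion-chain mean equations
  gnet <- griffith_network(d = 2)
  gg1 <- griffith_g1(0, 1)
  gp0 <- truncated_poisson(gnet, c(2, 3))
  gpt <- integrate_P(gnet, gg1, gp0, 6)
  ode2 <- ode_cascade(c(0, 6), c(2, 3), gnet$params$K * 1, gnet$params$a,
                      gnet$params$q)
  expect_equal(unname(lattice_mean(gpt)), unname(ode2[2, ]),
               tolerance = 1e-8)
})

test_that("lattice enlarges itself when mass reaches the boundary", {
  net <- switch_network()
  g1 <- switch_g1(0, 3) # strong production K m = 3
  p0 <- truncated_poisson(net, 2, nmax = 12) # deliberately tight lattice
  pt <- integrate_P(net, g1, p0, 30)
  expect_gt(pt$nmax, 12)
  ## mass conserved relative to what the (truncated) initial distribution
  ## actually carried
  expect_equal(sum(pt$p), sum(p0$p), tolerance = 1e-9)
})
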