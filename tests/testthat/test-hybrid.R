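test_that("sampled waiting time inverts the survival function", {
  net <- switch_network()
  ## xi1 -> 1 gives tau -> 0
  st <- hybrid_state(net, 0, 1, 10)
  expect_lt(sample_tau(st, 1 - 1e-12)$tau, 1e-10)
  ## pure-exponential regime: S2 occupied makes q_tilde = q, b2 = 0 when
  ## lambda sits at its fixed point, reducing to the direct-method formula
  p <- net$params
  lam_fix <- p$K * 2 / p$q
  st2 <- hybrid_state(net, 2, 2, lam_fix)
  er <- effective_rates_switch(switch_g1(2, 2), p)
  b1 <- er$K_tilde - p$K * 2
  ts <- sample_tau(st2, 0.41)
  expect_true(ts$fast)
  expect_equal(ts$tau, log(1 / 0.41) / b1, tolerance = 1e-12)
  ## exact path agrees with the lattice oracle's survival at the root
  st3 <- hybrid_state(net, 0, 1, 10)
  ts3 <- sample_tau(st3, 0.3, force_exact = TRUE)
  p0 <- truncated_poisson(net, 10, oracle_nmax(110))
  qq <- integrate_Q(net, switch_g1(0, 1), p0, ts3$tau)
  expect_lt(abs(qq$survival - 0.3), 1e-9)
})

test_that("silent simulated group yields the no-event sentinel", {
  p0 <- switch_params(alpha1 = 1e-300, alpha2 = 1e-300, beta1 = 1e-300,
                      beta2 = 1e-300, r0 = 1e-300, r = 1e-300, k = 1e-300)
  net <- switch_network(p0)
  st <- hybrid_state(net, 0, 0, 25)
  ## rates cannot be exactly zero in a valid network, so "silent" means a
  ## waiting time beyond any physical horizon
  expect_gt(sample_tau(st, 0.5)$tau, 1e12)
  expect_equal(fast_tau(0.5, 0, 0)$tau, NA_real_)
})

test_that("switch probabilities: occupied-promoter cases are exact ratios", {
  net <- switch_network()
  p <- net$params
  ## doubly occupied: no n dependence at all
  st <- hybrid_state(net, 2, 4, 50)
  pr <- reaction_probs_switch(st)
  km <- p$k * 4
  tot <- p$beta2 + p$r + km
  expect_equal(pr, c(0, 0, 0, p$beta2 / tot, p$r / tot, km / tot),
               tolerance = 1e-12)
  ## empty promoter, no mRNA: decay probability is zero
  st0 <- hybrid_state(net, 0, 0, 30)
  pr0 <- reaction_probs_switch(st0)
  expect_equal(pr0[6], 0)
  expect_equal(sum(pr0), 1, tolerance = 1e-9)
})

test_that("griffith probabilities: saturated promoter reduces to two channels", {
  net <- griffith_network(d = 10)
  p <- net$params
  st <- hybrid_state(net, 4, 3, c(rep(5, 9), 40))
  pr <- reaction_probs_griffith(st)
  km <- p$k * 3
  expect_equal(pr[8], p$beta4 / (p$beta4 + km), tolerance = 1e-12)
  expect_equal(pr[10], km / (p$beta4 + km), tolerance = 1e-12)
  expect_equal(sum(pr[-c(8, 10)]), 0)
  ## m = 0 leaves only unbinding
  st0 <- hybrid_state(net, 4, 0, c(rep(5, 9), 40))
  expect_equal(reaction_probs_griffith(st0)[8], 1)
})

test_that("closed-form probabilities match brute-force marginalization", {
  ## randomized fixture states, both models, exact inverse moments
  for (model in c("switch", "griffith")) {
    states <- generate_fixture("states", n = 25, seed = 33, model = model,
                               d = 6)
    for (st in states) {
      pr <- if (model == "switch") {
        reaction_probs_switch(st, inverse_moment = "exact")
      } else {
        reaction_probs_griffith(st, inverse_moment = "exact")
      }
      lam_free <- tail(st$lambda, 1)
      bru <- brute_reaction_probs(st$network,
                                  hybridCME:::g1_state_vector(st),
                                  lam_free)
      expect_lt(max(abs(pr - bru)), 1e-8)
      expect_lt(abs(sum(pr) - 1), 1e-9)
    }
  }
})

test_that("the printed griffith coefficient variant differs measurably", {
  net <- griffith_network(d = 4)
  st <- hybrid_state(net, 0, 3, c(2, 3, 4, 30))
  pr <- reaction_probs_griffith(st, inverse_moment = "exact")
  prv <- reaction_probs_griffith(st, inverse_moment = "exact",
                                 as_printed = TRUE)
  bru <- brute_reaction_probs(net, griffith_g1(0, 3), 30)
  expect_lt(max(abs(pr - bru)), 1e-8) # derived set matches the oracle
  expect_gt(max(abs(prv - bru)), 1e-3) # printed set does not
})

test_that("next-reaction selection walks the cumulative sums", {
  expect_equal(select_next_reaction(c(1, 0, 0), 0.999), 1)
  expect_equal(select_next_reaction(c(0.25, 0.75), 0.5), 2)
  expect_equal(select_next_reaction(c(0.25, 0.75), 0.2), 1)
  set.seed(4)
  p <- c(0.1, 0.6, 0.3)
  draws <- vapply(runif(2e4), function(u) select_next_reaction(p, u),
                  numeric(1))
  for (j in 1:3) {
    expect_lt(abs(mean(draws == j) - p[j]),
              3 * sqrt(p[j] * (1 - p[j]) / 2e4))
  }
})

test_that("distribution shifts conserve mass and pile up at zero", {
  p <- dpois(0:30, 3)
  ## decrement: P'(0) = P(0) + P(1), P'(n) = P(n + 1)
  d1 <- shift_distribution_down(p, 1)
  expect_equal(d1[1], p[1] + p[2])
  expect_equal(d1[2:30], p[3:31])
  expect_equal(sum(d1), sum(p))
  ## delta at 5 shifts to delta at 4
  del <- c(rep(0, 5), 1, rep(0, 10))
  expect_equal(which(shift_distribution_down(del, 1) == 1) - 1, 4)
  expect_equal(which(shift_distribution_up(del, 2) == 1) - 1, 7)
  ## up-shift refuses to push mass off the lattice
  expect_error(shift_distribution_up(c(0, 0, 1), 1), "off the lattice")
})

test_that("applying a reaction advances the state per stoichiometry", {
  net <- switch_network()
  st <- hybrid_state(net, 0, 2, 10)
  ## transcription: m increments, lambda advanced by the closed form
  st2 <- apply_reaction_and_reset(st, 5, 3)
  expect_equal(st2$m, 3)
  expect_equal(st2$promoter, 0L)
  expect_equal(st2$lambda,
               lambda_switch(3, 10, net$params$K, 2, net$params$q))
  expect_equal(st2$t, 3)
  ## binding flips the promoter up
  st3 <- apply_reaction_and_reset(st, 1, 0.5)
  expect_equal(st3$promoter, 1L)
})

test_that("exact-mode step agrees with the closed forms for Poisson input", {
  net <- switch_network()
  g1 <- switch_g1(0, 1)
  dist <- truncated_poisson(net, 10, oracle_nmax(110))
  step <- hybrid_step_exact(net, g1, dist, xi1 = 0.4, xi2 = 0.15)
  st <- hybrid_state(net, 0, 1, 10)
  ts <- sample_tau(st, 0.4, force_exact = TRUE)
  expect_equal(step$tau, ts$tau, tolerance = 1e-6)
  pr <- reaction_probs_switch(hybridCME:::within_advance(st, ts$tau),
                              inverse_moment = "exact")
  expect_equal(step$mu, select_next_reaction(pr, 0.15))
  expect_lt(step$survival_check, 1e-8)
})

test_that("compiled and R reference loops agree statistically", {
  net <- switch_network()
  grid <- seq(0, 120, 10)
  hy <- simulate_hybrid(net, t_final = 120, seed = 5, record_times = grid,
                        n_real = 400)
  mu_c <- apply(hy[, "m", ], 1, mean)
  se_c <- apply(hy[, "m", ], 1, sd) / sqrt(400)
  set.seed(60)
  mr <- replicate(60, run_hybrid_r(net, t_final = 120,
                                   seed = sample.int(1e6, 1),
                                   record_times = grid)[, "m"])
  mu_r <- rowMeans(mr)
  se_r <- apply(mr, 1, sd) / sqrt(60)
  z <- (mu_c - mu_r) / sqrt(se_c^2 + se_r^2 + 1e-12)
  expect_true(all(abs(z[-1]) < 4))
})

test_that("hybrid trajectories are seed-reproducible", {
  net <- griffith_network(d = 10)
  a <- simulate_hybrid(net, t_final = 100, seed = 8,
                       record_times = seq(0, 100, 10), n_real = 3)
  b <- simulate_hybrid(net, t_final = 100, seed = 8,
                       record_times = seq(0, 100, 10), n_real = 3)
  expect_identical(a, b)
  cnt <- attr(a, "counters")
  expect_true(all(cnt[, "events"] > 0))
  expect_true(all(cnt[, "fast_path"] + cnt[, "exact_root"] >=
                    cnt[, "events"]))
})
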