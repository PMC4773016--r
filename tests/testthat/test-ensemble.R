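make_states <- function(mat_list, times) {
  ## build an ensemble_states array from a list of [time x var] matrices
  arr <- array(unlist(mat_list),
               dim = c(nrow(mat_list[[1]]), ncol(mat_list[[1]]),
                       length(mat_list)))
  dimnames(arr) <- list(NULL, colnames(mat_list[[1]]), NULL)
  structure(arr, times = times, model = "toy", seed = 0,
            class = "ensemble_states")
}

test_that("summaries have the exact trivial limits", {
  tm <- 0:4
  m1 <- cbind(m = c(0, 1, 2, 3, 4))
  s <- summarize_ensemble(make_states(list(m1, m1), tm))
  expect_equal(unname(s$sd[, "m"]), rep(0, 5))
  s2 <- summarize_ensemble(make_states(list(cbind(m = rep(0, 5)),
                                            cbind(m = rep(2, 5))), tm))
  expect_equal(unname(s2$mean[, "m"]), rep(1, 5))
  expect_error(summarize_ensemble(make_states(list(m1), tm)), "dim")
})

test_that("comparison of an ensemble with itself gives zero z everywhere", {
  net <- switch_network()
  x <- simulate_ssa(net, t_final = 40, seed = 2,
                    record_times = seq(0, 40, 5), n_real = 50)
  s <- summarize_ensemble(x, histogram_times = 20)
  cmp <- compare_ensembles(s, s)
  expect_equal(max(abs(cmp$z_mean)), 0)
  expect_equal(max(abs(cmp$z_sd)), 0)
  expect_gt(cmp$chisq$p_value[1], 0.999)
  ## grid mismatch is rejected
  y <- simulate_ssa(net, t_final = 40, seed = 2,
                    record_times = seq(0, 40, 10), n_real = 50)
  expect_error(compare_ensembles(s, summarize_ensemble(y)), "common")
})

test_that("independent exact ensembles sit inside the self-consistency band", {
  net <- switch_network()
  grid <- seq(0, 150, 5)
  a <- simulate_ssa(net, t_final = 150, seed = 14, record_times = grid,
                    n_real = 500)
  b <- simulate_ssa(net, t_final = 150, seed = 14, record_times = grid,
                    n_real = 500, stream_offset = 500)
  cmp <- compare_ensembles(summarize_ensemble(a), summarize_ensemble(b))
  expect_gt(mean(abs(cmp$z_mean) <= 3), 0.99)
  ## dispersion z-scores are heavier-tailed at this ensemble size (the
  ## fourth-moment standard error is itself noisy); allow a slightly
  ## wider exceedance rate than for the means
  expect_gt(mean(abs(cmp$z_sd) <= 3), 0.98)
  ## symmetry up to sign
  cmp2 <- compare_ensembles(summarize_ensemble(b), summarize_ensemble(a))
  expect_equal(cmp2$z_mean, -cmp$z_mean)
})

test_that("hidden-mean recovery solves the driven linear system", {
  p <- switch_params()
  tm <- seq(0, 200, 2)
  ## no drive: exponential decay from n0
  n <- recover_hidden_mean(tm, rep(0, length(tm)), p, "switch", n0 = 40)
  expect_equal(unname(n[, 1]), 40 * exp(-p$q * tm), tolerance = 1e-6)
  ## constant drive: relaxation to K c / q
  n2 <- recover_hidden_mean(tm, rep(3, length(tm)), p, "switch")
  expect_equal(unname(n2[nrow(n2), 1]), p$K * 3 / p$q * (1 - exp(-p$q * 200)),
               tolerance = 1e-6)
  ## linearity: response to a sum is the sum of responses
  m1 <- sin(tm / 30)^2
  m2 <- exp(-tm / 50)
  r1 <- recover_hidden_mean(tm, m1, p, "switch")
  r2 <- recover_hidden_mean(tm, m2, p, "switch")
  r12 <- recover_hidden_mean(tm, m1 + m2, p, "switch")
  expect_equal(unname(r12[, 1]), unname(r1[, 1] + r2[, 1]),
               tolerance = 1e-6)
  ## griffith chain reaches the cascade fixed point under constant drive
  gp <- griffith_params()
  tg <- seq(0, 4000, 10)
  ng <- recover_hidden_mean(tg, rep(2, length(tg)), gp, "griffith", d = 5)
  expect_equal(unname(ng[nrow(ng), ]),
               c(rep(gp$K * 2 / gp$a, 4), gp$K * 2 / gp$q),
               tolerance = 1e-4)
})

test_that("writers emit headered tab-separated tables round-trippably", {
  net <- switch_network()
  x <- simulate_ssa(net, t_final = 20, seed = 1,
                    record_times = seq(0, 20, 2), n_real = 5)
  td <- withr::local_tempdir()
  tp <- file.path(td, "traj.tsv")
  write_trajectory(x, tp, 2)
  df <- read.delim(tp)
  expect_equal(names(df), c("time", "S0", "S1", "S2", "m", "n"))
  expect_equal(df$m, unname(x[, "m", 2]))
  s <- summarize_ensemble(x, histogram_times = 10)
  sp <- file.path(td, "summ.tsv")
  write_ensemble_summary(s, sp)
  ds <- read.delim(sp)
  expect_true(all(c("mean_m", "std_m") %in% names(ds)))
  hp <- file.path(td, "hist.tsv")
  write_histograms(s, hp)
  dh <- read.delim(hp)
  expect_equal(sum(dh$probability), 1, tolerance = 1e-12)
})
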