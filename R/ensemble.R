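#' Summarize an ensemble of trajectories
#'
#' Pointwise mean and standard deviation (sample convention, `n - 1`) of
#' every recorded variable over realizations, plus unit-bin histograms of
#' selected variables at selected times. Second and fourth central moments
#' are retained so that comparisons can attach standard errors to the
#' standard deviations without normality assumptions.
#'
#' @param x An `ensemble_states` array from [simulate_ssa()] or
#'   [simulate_hybrid()].
#' @param histogram_times Times (matched to the nearest grid point) at
#'   which unit-bin histograms are recorded.
#' @param histogram_vars Variables to histogram (default `"m"`).
#' @return An `ensemble_summary`: list with `times`, `vars`, `n`, matrices
#'   `mean`, `sd`, `m2`, `m4` (`times x vars`), and `histograms` (nested
#'   list time -> variable -> named count table).
#' @export
summarize_ensemble <- function(x, histogram_times = NULL,
                               histogram_vars = "m") {
  stopifnot(inherits(x, "ensemble_states"), dim(x)[3] >= 2)
  times <- attr(x, "times")
  vars <- dimnames(x)[[2]]
  n <- dim(x)[3]
  mu <- apply(x, c(1, 2), mean)
  dev <- sweep(x, c(1, 2), mu)
  m2 <- apply(dev^2, c(1, 2), sum) / n
  m4 <- apply(dev^4, c(1, 2), sum) / n
  sdev <- sqrt(m2 * n / (n - 1))
  dimnames(mu) <- dimnames(sdev) <- dimnames(m2) <- dimnames(m4) <-
    list(NULL, vars)
  hists <- list()
  for (ht in histogram_times) {
    gi <- which.min(abs(times - ht))
    hl <- list()
    for (v in histogram_vars) {
      cnt <- table(factor(round(x[gi, v, ])))
      hl[[v]] <- cnt
    }
    hists[[format(times[gi])]] <- hl
  }
  structure(list(times = times, vars = vars, n = n, mean = mu, sd = sdev,
                 m2 = m2, m4 = m4, histograms = hists,
                 seed = attr(x, "seed"), model = attr(x, "model")),
            class = "ensemble_summary")
}

#' @exportS3Method base::print
print.ensemble_summary <- function(x, ...) {
  cat("<ensemble_summary>", x$model, "| n =", x$n, "|",
      length(x$times), "times |", paste(x$vars, collapse = ", "), "\n")
  invisible(x)
}

## standard error of the mean and of the sd (delta method on the variance,
## no normality assumption)
se_mean <- function(s) s$sd / sqrt(s$n)
se_sd <- function(s) {
  v <- pmax(s$m4 - s$m2^2, 0) / s$n # Var(sample variance), leading order
  out <- sqrt(v) / (2 * s$sd)
  out[s$sd == 0] <- 0
  out
}

#' Compare two trajectory ensembles
#'
#' Per-grid-point z-scores of the difference in means and in standard
#' deviations (difference over quadrature-combined standard errors), and
#' two-sample chi-square tests on unit-bin histograms recorded at matching
#' times. With the conventional +-3 band and many correlated grid points,
#' occasional boundary excursions are expected by chance; the `max_abs_z`
#' fields are the conservative summary.
#'
#' @param A,B `ensemble_summary` objects on a common grid. Variables are
#'   compared where names match (Poisson-mean columns of the hybrid are
#'   ignored unless present in both).
#' @param min_expected Minimum pooled expected count per chi-square bin;
#'   adjacent unit bins are merged until it is met.
#' @return An `ensemble_comparison`: matrices `z_mean`, `z_sd`, the
#'   summary `max_abs_z_mean`, `max_abs_z_sd`, and a data frame
#'   `chisq` (time, var, statistic, df, p_value).
#' @export
compare_ensembles <- function(A, B, min_expected = 5) {
  stopifnot(inherits(A, "ensemble_summary"), inherits(B, "ensemble_summary"))
  if (!isTRUE(all.equal(A$times, B$times))) {
    stop("ensembles are not on a common time grid", call. = FALSE)
  }
  vars <- intersect(A$vars, B$vars)
  zden_m <- sqrt(se_mean(A)[, vars, drop = FALSE]^2 +
                   se_mean(B)[, vars, drop = FALSE]^2)
  dm <- A$mean[, vars, drop = FALSE] - B$mean[, vars, drop = FALSE]
  z_mean <- dm / zden_m
  z_mean[dm == 0] <- 0
  zden_s <- sqrt(se_sd(A)[, vars, drop = FALSE]^2 +
                   se_sd(B)[, vars, drop = FALSE]^2)
  ds <- A$sd[, vars, drop = FALSE] - B$sd[, vars, drop = FALSE]
  z_sd <- ds / zden_s
  z_sd[ds == 0] <- 0
  chs <- NULL
  common_t <- intersect(names(A$histograms), names(B$histograms))
  for (tn in common_t) {
    for (v in intersect(names(A$histograms[[tn]]),
                        names(B$histograms[[tn]]))) {
      ct <- chisq_two_sample(A$histograms[[tn]][[v]],
                             B$histograms[[tn]][[v]], min_expected)
      chs <- rbind(chs, data.frame(time = as.numeric(tn), var = v,
                                   statistic = ct$statistic, df = ct$df,
                                   p_value = ct$p_value))
    }
  }
  structure(list(times = A$times, vars = vars, z_mean = z_mean,
                 z_sd = z_sd,
                 max_abs_z_mean = max(abs(z_mean), na.rm = TRUE),
                 max_abs_z_sd = max(abs(z_sd), na.rm = TRUE),
                 chisq = chs, n_A = A$n, n_B = B$n),
            class = "ensemble_comparison")
}

#' @exportS3Method base::print
print.ensemble_comparison <- function(x, ...) {
  cat("<ensemble_comparison> max |z| mean:",
      format(x$max_abs_z_mean, digits = 3), "| max |z| sd:",
      format(x$max_abs_z_sd, digits = 3), "\n")
  if (!is.null(x$chisq)) {
    cat("  chi-square p-values:",
        paste(format(x$chisq$p_value, digits = 3), collapse = ", "), "\n")
  }
  invisible(x)
}

## two-sample chi-square over the union support with greedy pooling of
## adjacent unit bins to a minimum pooled count
chisq_two_sample <- function(tabA, tabB, min_expected = 5) {
  support <- sort(unique(as.numeric(c(names(tabA), names(tabB)))))
  full <- seq(min(support), max(support))
  cA <- setNames(numeric(length(full)), full)
  cB <- cA
  cA[names(tabA)] <- as.numeric(tabA)
  cB[names(tabB)] <- as.numeric(tabB)
  ## greedy pooling left to right
  pa <- pb <- numeric(0)
  accA <- accB <- 0
  for (i in seq_along(full)) {
    accA <- accA + cA[i]; accB <- accB + cB[i]
    if (accA + accB >= 2 * min_expected) {
      pa <- c(pa, accA); pb <- c(pb, accB)
      accA <- accB <- 0
    }
  }
  if (accA + accB > 0) { # fold the remainder into the last bin
    if (length(pa) == 0) { pa <- accA; pb <- accB }
    else { pa[length(pa)] <- pa[length(pa)] + accA
           pb[length(pb)] <- pb[length(pb)] + accB }
  }
  tab <- cbind(pa, pb)
  nA <- sum(pa); nB <- sum(pb); tot <- nA + nB
  e <- outer(rowSums(tab), c(nA, nB) / tot)
  stat <- sum((tab - e)^2 / e)
  df <- max(nrow(tab) - 1, 1)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Recover the mean of the hidden (analytic) species
#'
#' The ensemble mean of the non-simulated species obeys a closed linear
#' system driven by the simulated mRNA mean: for the switch
#' `nbar' = K*mbar - q*nbar`; for the oscillator the conversion chain
#' `nbar1' = K*mbar - a*nbar1`, ..., `nbard' = a*nbar(d-1) - q*nbard`.
#' Integrating it with the hybrid's `mbar(t)` recovers the protein mean
#' that the hybrid never simulates. The map is linear in `mbar`.
#'
#' @param times Time grid of `m_mean`.
#' @param m_mean Ensemble-mean mRNA trajectory.
#' @param params Model rates.
#' @param model `"switch"` or `"griffith"`.
#' @param d Cascade length (Griffith).
#' @param n0 Initial mean(s) of the hidden species (default 0).
#' @return Matrix `times x species` of recovered means (single column for
#'   the switch).
#' @export
recover_hidden_mean <- function(times, m_mean, params,
                                model = c("switch", "griffith"), d = 10,
                                n0 = NULL) {
  model <- match.arg(model)
  mfun <- approxfun(times, m_mean, rule = 2)
  if (model == "switch") {
    if (is.null(n0)) n0 <- 0
    rhs <- function(t, y, p) list(params$K * mfun(t) - params$q * y)
    out <- deSolve::ode(y = c(n = n0), times = times, func = rhs,
                        parms = NULL, rtol = 1e-10, atol = 1e-10)
    out[, -1, drop = FALSE]
  } else {
    if (is.null(n0)) n0 <- numeric(d)
    rhs <- function(t, y, p) {
      dn <- c(params$K * mfun(t) - params$a * y[1],
              if (d > 2) params$a * (y[seq_len(d - 2)] - y[1 + seq_len(d - 2)]),
              params$a * y[d - 1] - params$q * y[d])
      list(dn)
    }
    out <- deSolve::ode(y = setNames(n0, paste0("n", seq_len(d))),
                        times = times, func = rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-10)
    out[, -1, drop = FALSE]
  }
}
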