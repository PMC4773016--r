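## Run configuration: a flat key: value text file plus programmatic
## overrides, with model defaults taken from the built-in parameter sets.

run_config_defaults <- function() {
  list(model = "switch", method = "cmega", t_final = 500, ensemble = 1,
       record_dt = 5, histogram_times = numeric(0), seed = 1,
       eps = 0.001, inverse_moment = "auto", d = 10,
       qtilde_printed = FALSE, out_dir = ".")
}

#' Parse a run configuration
#'
#' Reads a flat `key: value` text file (blank lines and `#` comments
#' ignored) and/or a list of overrides (overrides win). Recognized keys:
#' `model` (switch | griffith), `method` (ga | cmega | oracle-check),
#' `t_final`, `ensemble`, `record_dt`, `histogram_times` (comma
#' separated), `seed`, `eps`, `inverse_moment` (auto | exact), `d`,
#' `qtilde_printed`, `out_dir`, plus any rate constant of the chosen
#' model (e.g. `alpha1`, `r0`). Unknown keys and invalid values are
#' rejected with a descriptive error.
#'
#' @param file Optional path to the config file.
#' @param overrides Named list (e.g. from command-line flags).
#' @return A validated `run_config` list, with `params` filled from the
#'   model defaults and any rate overrides.
#' @export
parse_run_config <- function(file = NULL, overrides = list()) {
  kv <- list()
  if (!is.null(file)) {
    lines <- readLines(file, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*[:=]\\s*(.*)$", ln))[[1]]
      if (length(m) != 3) stop("cannot parse config line: ", ln,
                               call. = FALSE)
      kv[[m[2]]] <- trimws(m[3])
    }
  }
  kv[names(overrides)] <- overrides
  cfg <- run_config_defaults()
  model <- if (!is.null(kv$model)) as.character(kv$model) else cfg$model
  if (!model %in% c("switch", "griffith")) {
    stop("unknown model: ", model, call. = FALSE)
  }
  rate_names <- if (model == "switch") {
    names(formals(switch_params))
  } else {
    names(formals(griffith_params))
  }
  known <- c(names(cfg), rate_names)
  unknown <- setdiff(names(kv), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  num <- function(x) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) stop("not a number: ", x, call. = FALSE)
    v
  }
  for (k in names(kv)) {
    cfg[[k]] <- switch(k,
      model = , method = , inverse_moment = , out_dir = as.character(kv[[k]]),
      qtilde_printed = as.logical(kv[[k]]),
      histogram_times = if (is.numeric(kv[[k]])) kv[[k]] else {
        num(strsplit(as.character(kv[[k]]), ",")[[1]])
      },
      num(kv[[k]]))
  }
  if (!cfg$method %in% c("ga", "cmega", "oracle-check")) {
    stop("method must be ga, cmega or oracle-check", call. = FALSE)
  }
  if (!cfg$inverse_moment %in% c("auto", "exact")) {
    stop("inverse_moment must be auto or exact", call. = FALSE)
  }
  if (cfg$t_final <= 0) stop("t_final must be > 0", call. = FALSE)
  if (cfg$ensemble < 1) stop("ensemble must be >= 1", call. = FALSE)
  if (cfg$eps <= 0) stop("eps must be > 0", call. = FALSE)
  rates <- cfg[intersect(names(cfg), rate_names)]
  cfg$params <- if (model == "switch") {
    do.call(switch_params, rates)
  } else {
    do.call(griffith_params, rates[setdiff(names(rates), "d")])
  }
  cfg[setdiff(rate_names, "d")] <- NULL
  cfg$model <- model
  structure(cfg, class = "run_config")
}

#' Execute a configured run
#'
#' Builds the model network, runs the requested method (`ga` for the
#' exact full-network simulation, `cmega` for the hybrid,
#' `oracle-check` for the closed-form verification battery), and writes
#' tab-separated artifacts into `out_dir`: per-realization trajectories
#' (ensembles of at most 50), the ensemble summary (ensembles of at
#' least 2), histograms if requested, and a structured `run_log.tsv`
#' with the seed and per-run counters (events, fast-path acceptances,
#' exact-root fallbacks). Everything written is a pure function of the
#' configuration, including the seed.
#'
#' @param config A `run_config` from [parse_run_config()].
#' @return Invisibly, a list with the in-memory results (`states`,
#'   `summary` or `checks`) and the paths written.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  if (config$method == "oracle-check") {
    checks <- oracle_check(config$model, d = min(config$d, 3))
    path <- file.path(config$out_dir, "oracle_check.tsv")
    write.table(checks, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(list(checks = checks, paths = path)))
  }
  net <- if (config$model == "switch") {
    switch_network(config$params)
  } else {
    griffith_network(config$params, d = config$d)
  }
  grid <- seq(0, config$t_final, by = config$record_dt)
  x <- if (config$method == "ga") {
    simulate_ssa(net, t_final = config$t_final, seed = config$seed,
                 record_times = grid, n_real = config$ensemble)
  } else {
    simulate_hybrid(net, t_final = config$t_final, seed = config$seed,
                    record_times = grid, n_real = config$ensemble,
                    eps = config$eps,
                    inverse_moment = config$inverse_moment,
                    qtilde_printed = config$qtilde_printed)
  }
  paths <- character(0)
  if (config$ensemble <= 50) {
    for (i in seq_len(config$ensemble)) {
      p <- file.path(config$out_dir, sprintf("trajectory_%03d.tsv", i))
      write_trajectory(x, p, i)
      paths <- c(paths, p)
    }
  }
  summ <- NULL
  if (config$ensemble >= 2) {
    summ <- summarize_ensemble(x, histogram_times = config$histogram_times)
    p <- file.path(config$out_dir, "summary.tsv")
    write_ensemble_summary(summ, p)
    paths <- c(paths, p)
    if (length(config$histogram_times)) {
      p <- file.path(config$out_dir, "histograms.tsv")
      write_histograms(summ, p)
      paths <- c(paths, p)
    }
  }
  cnt <- attr(x, "counters")
  log <- data.frame(
    key = c("model", "method", "seed", "ensemble", "t_final",
            "wall_seconds", "events_total", "fast_path_total",
            "exact_root_total", "im_fallback_total"),
    value = c(config$model, config$method, config$seed, config$ensemble,
              config$t_final,
              round(proc.time()[["elapsed"]] - t0, 3),
              if (is.null(cnt)) rep(NA, 4) else colSums(cnt)))
  p <- file.path(config$out_dir, "run_log.tsv")
  write.table(log, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  invisible(list(states = x, summary = summ, paths = paths))
}

#' Closed-form verification battery
#'
#' Re-derives the analytic machinery numerically and reports residuals:
#' Poisson preservation of the normalized lattice solution, survival
#' function against the unnormalized lattice solution, and marginalized
#' reaction probabilities against brute-force lattice summation.
#'
#' @param model `"switch"` or `"griffith"`.
#' @param d Cascade length for the oscillator lattice (kept small; the
#'   joint lattice grows geometrically).
#' @param seed Seed for the randomized states.
#' @return Data frame `check`, `value`, `tol`, `pass`.
#' @export
oracle_check <- function(model = c("switch", "griffith"), d = 2,
                         seed = 1) {
  model <- match.arg(model)
  set.seed(seed)
  if (model == "switch") {
    net <- switch_network()
    g1 <- c(S0 = 1, S1 = 0, S2 = 0, m = 1)
    lam0 <- 10
    p0 <- truncated_poisson(net, lam0, oracle_nmax(110))
    ## Poisson preservation at t = 10
    pt <- integrate_P(net, g1, p0, 10)
    lam_t <- lambda_switch(10, lam0, net$params$K, 1, net$params$q)
    tv <- 0.5 * sum(abs(pt$p - dpois(0:pt$nmax, lam_t)))
    ## survival at tau = 2
    qres <- integrate_Q(net, g1, p0, 2)
    sv <- abs(qres$survival - survival_switch(2, lam0, g1))
    ## probabilities at a randomized state
    st <- hybrid_state(net, promoter = sample(0:2, 1), m = sample(0:5, 1),
                       lambda = runif(1, 5, 80))
    pr <- reaction_probs_switch(st, inverse_moment = "exact")
    bru <- marginal_reaction_probs(
      net, g1_state_vector(st),
      truncated_poisson(net, st$lambda, oracle_nmax(st$lambda)))
    pe <- max(abs(pr - bru))
    checks <- data.frame(
      check = c("poisson_preservation_tv", "survival_abs_err",
                "reaction_probs_abs_err"),
      value = c(tv, sv, pe),
      tol = c(1e-8, 1e-6, 1e-8))
  } else {
    net <- griffith_network(d = d)
    g1 <- setNames(numeric(6), c(paste0("S", 0:4), "m"))
    g1["S0"] <- 1; g1["m"] <- 2
    lam0 <- runif(d, 1, 4)
    p0 <- truncated_poisson(net, lam0)
    pt <- integrate_P(net, g1, p0, 5)
    lam_t <- lambda_griffith(5, lam0, net$params$K, 2, net$params$a,
                             net$params$q)
    exp_p <- truncated_poisson(net, lam_t, pt$nmax)$p
    tv <- 0.5 * sum(abs(pt$p - exp_p))
    qres <- integrate_Q(net, g1, p0, 2)
    sv <- abs(qres$survival - survival_griffith(2, lam0, g1, net$params))
    st <- hybrid_state(net, promoter = 1, m = 2, lambda = lam0)
    pr <- reaction_probs_griffith(st, inverse_moment = "exact")
    bru <- marginal_reaction_probs(net, g1_state_vector(st), p0)
    pe <- max(abs(pr - bru))
    checks <- data.frame(
      check = c("poisson_preservation_tv", "survival_abs_err",
                "reaction_probs_abs_err"),
      value = c(tv, sv, pe),
      tol = c(1e-8, 1e-6, 1e-8))
  }
  checks$pass <- checks$value < checks$tol
  checks
}

#' Generate randomized fixtures for property tests
#'
#' Deterministic (seeded) random parameter sets and hybrid states
#' satisfying all type invariants; used by the property-based tests that
#' compare the closed-form reaction probabilities against brute-force
#' marginalization.
#'
#' @param kind `"params"` or `"states"`.
#' @param n Number of fixtures.
#' @param seed RNG seed.
#' @param model `"switch"` or `"griffith"`.
#' @param d Cascade length (Griffith states).
#' @return A list of parameter lists, or a list of `hybrid_state`s.
#' @export
generate_fixture <- function(kind = c("params", "states"), n = 10,
                             seed = 1, model = c("switch", "griffith"),
                             d = 10) {
  kind <- match.arg(kind)
  model <- match.arg(model)
  set.seed(seed)
  base <- if (model == "switch") switch_params() else griffith_params()
  if (kind == "params") {
    lapply(seq_len(n), function(i) {
      p <- lapply(base, function(v) v * 10^runif(1, -0.3, 0.3))
      do.call(if (model == "switch") switch_params else griffith_params, p)
    })
  } else {
    net <- if (model == "switch") switch_network() else {
      griffith_network(d = d)
    }
    npr <- if (model == "switch") 2 else 4
    lapply(seq_len(n), function(i) {
      hybrid_state(net, promoter = sample(0:npr, 1), m = sample(0:8, 1),
                   lambda = if (model == "switch") runif(1, 0, 150) else {
                     runif(d, 0, 60)
                   })
    })
  }
}
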