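#' @useDynLib hybridCME, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approxfun dpois qpois rpois runif sd setNames chisq.test
#'   ks.test pchisq uniroot
#' @importFrom utils write.table head tail
"_PACKAGE"

## A reaction network is a list:
##   species   : data.frame(name, group ("G1"/"G2"), kind ("count"/"indicator"))
##   reactions : list of reactions, each
##       list(name, group, terms = list(list(coef, species = character())),
##            stoich = named integer vector over all species)
##   params, model ("switch"/"griffith"), d (griffith)
## Propensities are mass-action: each reaction's propensity is a sum of terms
## coef * prod(counts of listed species).  A compound propensity (several
## terms) is used for the switch transcription channel so the simulated
## reaction list matches the 6-way grouping used by the reaction-probability
## closed forms.

new_reaction <- function(name, group, terms, stoich) {
  list(name = name, group = group, terms = terms, stoich = stoich)
}

#' Build the genetic switch network
#'
#' Constructs the 10-reaction network of the autoregulated switch with the
#' promoter indicators `S0`, `S1`, `S2`, the mRNA `m` (all simulated, group
#' G1) and the protein `n` (analytically propagated, group G2). The six G1
#' channels are: two bindings, two unbindings, transcription (one channel
#' with compound propensity `r0*S0 + r0*S1 + r*S2`) and mRNA decay; the two
#' G2 channels are translation (`K*m`) and protein decay (`q*n`).
#'
#' @param params Named list of rates from [switch_params()].
#' @return An object of class `reaction_network`.
#' @examples
#' net <- switch_network()
#' propensities(net, c(S0 = 1, S1 = 0, S2 = 0, m = 2, n = 100))
#' @export
switch_network <- function(params = switch_params()) {
  params <- do.call(switch_params, params[names(formals(switch_params))[
    names(formals(switch_params)) %in% names(params)]])
  sp <- data.frame(
    name  = c("S0", "S1", "S2", "m", "n"),
    group = c("G1", "G1", "G1", "G1", "G2"),
    kind  = c("indicator", "indicator", "indicator", "count", "count"),
    stringsAsFactors = FALSE)
  z <- setNames(integer(5), sp$name)
  st <- function(...) { v <- z; a <- list(...); v[names(a)] <- unlist(a); v }
  with(params, {
    rx <- list(
      new_reaction("bind1", "G1",
                   list(list(coef = alpha1, species = c("S0", "n"))),
                   st(S0 = -1L, S1 = 1L, n = -1L)),
      new_reaction("unbind1", "G1",
                   list(list(coef = beta1, species = "S1")),
                   st(S1 = -1L, S0 = 1L, n = 1L)),
      new_reaction("bind2", "G1",
                   list(list(coef = alpha2, species = c("S1", "n"))),
                   st(S1 = -1L, S2 = 1L, n = -1L)),
      new_reaction("unbind2", "G1",
                   list(list(coef = beta2, species = "S2")),
                   st(S2 = -1L, S1 = 1L, n = 1L)),
      new_reaction("transcription", "G1",
                   list(list(coef = r0, species = "S0"),
                        list(coef = r0, species = "S1"),
                        list(coef = r,  species = "S2")),
                   st(m = 1L)),
      new_reaction("mrna_decay", "G1",
                   list(list(coef = k, species = "m")),
                   st(m = -1L)),
      new_reaction("translation", "G2",
                   list(list(coef = K, species = "m")),
                   st(n = 1L)),
      new_reaction("protein_decay", "G2",
                   list(list(coef = q, species = "n")),
                   st(n = -1L)))
    structure(list(species = sp, reactions = rx, params = params,
                   model = "switch"),
              class = "reaction_network")
  })
}

#' Build the Griffith oscillator network
#'
#' Constructs the Griffith-type oscillator with promoter indicators
#' `S0` ... `S4`, mRNA `m` (simulated, G1) and a `d`-step protein conversion
#' cascade `n1` ... `nd` (analytic, G2). The ten G1 channels are four
#' bindings of the mature conformation `nd`, four unbindings, transcription
#' `r*S0` and mRNA decay `k*m`; G2 holds translation into `n1`, the `d - 1`
#' conversions `a*ni` and mature-protein decay `q*nd`.
#'
#' @param params Named list of rates from [griffith_params()].
#' @param d Number of protein conformations (at least 2).
#' @return An object of class `reaction_network`.
#' @export
griffith_network <- function(params = griffith_params(), d = 10) {
  params <- do.call(griffith_params, params[names(formals(griffith_params))[
    names(formals(griffith_params)) %in% names(params)]])
  if (!is.numeric(d) || length(d) != 1L || d != round(d) || d < 2) {
    stop("d must be an integer >= 2", call. = FALSE)
  }
  d <- as.integer(d)
  ncas <- paste0("n", seq_len(d))
  sp <- data.frame(
    name  = c(paste0("S", 0:4), "m", ncas),
    group = c(rep("G1", 6), rep("G2", d)),
    kind  = c(rep("indicator", 5), rep("count", d + 1)),
    stringsAsFactors = FALSE)
  z <- setNames(integer(nrow(sp)), sp$name)
  st <- function(nm, val) { v <- z; v[nm] <- as.integer(val); v }
  nd <- ncas[d]
  al <- unlist(params[paste0("alpha", 1:4)])
  be <- unlist(params[paste0("beta", 1:4)])
  ## order fixed as: bind1, unbind1, ..., bind4, unbind4, transcription,
  ## mRNA decay -- the 10-way grouping used by the reaction probabilities
  rx <- list()
  for (i in 1:4) {
    rx[[length(rx) + 1L]] <- new_reaction(
      paste0("bind", i), "G1",
      list(list(coef = al[[i]], species = c(paste0("S", i - 1), nd))),
      st(c(paste0("S", i - 1), paste0("S", i), nd), c(-1, 1, -1)))
    rx[[length(rx) + 1L]] <- new_reaction(
      paste0("unbind", i), "G1",
      list(list(coef = be[[i]], species = paste0("S", i))),
      st(c(paste0("S", i), paste0("S", i - 1), nd), c(-1, 1, 1)))
  }
  rx[[9]] <- new_reaction("transcription", "G1",
                          list(list(coef = params$r, species = "S0")),
                          st("m", 1))
  rx[[10]] <- new_reaction("mrna_decay", "G1",
                           list(list(coef = params$k, species = "m")),
                           st("m", -1))
  rx[[11]] <- new_reaction("translation", "G2",
                           list(list(coef = params$K, species = "m")),
                           st("n1", 1))
  for (i in seq_len(d - 1)) {
    rx[[length(rx) + 1L]] <- new_reaction(
      paste0("convert", i), "G2",
      list(list(coef = params$a, species = ncas[i])),
      st(ncas[i + 0:1], c(-1, 1)))
  }
  rx[[length(rx) + 1L]] <- new_reaction(
    "mature_decay", "G2",
    list(list(coef = params$q, species = nd)),
    st(nd, -1))
  structure(list(species = sp, reactions = rx, params = params,
                 model = "griffith", d = d),
            class = "reaction_network")
}

#' Evaluate reaction propensities
#'
#' Mass-action propensities of every reaction of a network at a given state.
#'
#' @param network A `reaction_network`.
#' @param state Named numeric vector of copy numbers (all species).
#' @param group Optional, `"G1"` or `"G2"` to restrict to one group.
#' @return Named numeric vector of propensities (per minute).
#' @export
propensities <- function(network, state, group = NULL) {
  rx <- network$reactions
  if (!is.null(group)) rx <- Filter(function(r) r$group == group, rx)
  vapply(rx, function(r) {
    sum(vapply(r$terms, function(tm) {
      tm$coef * prod(state[tm$species])
    }, numeric(1)))
  }, numeric(1)) -> a
  names(a) <- vapply(rx, `[[`, character(1), "name")
  if (any(a < 0) || anyNA(a)) {
    stop("propensity evaluated negative or NA; invalid state", call. = FALSE)
  }
  a
}

#' Validate a reaction network's partition invariants
#'
#' Checks that every stoichiometry vector covers every species, that G2
#' reactions leave all G1 species unchanged, and that promoter indicators are
#' one-hot in the supplied state (if given).
#'
#' @param network A `reaction_network`.
#' @param state Optional state to check the one-hot promoter invariant on.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_network <- function(network, state = NULL) {
  sp <- network$species$name
  g1 <- network$species$name[network$species$group == "G1"]
  for (r in network$reactions) {
    if (!identical(sort(names(r$stoich)), sort(sp))) {
      stop("reaction ", r$name, ": stoichiometry does not cover all species")
    }
    if (r$group == "G2" && any(r$stoich[g1] != 0L)) {
      stop("G2 reaction ", r$name, " changes a G1 species")
    }
  }
  if (!is.null(state)) {
    ind <- network$species$name[network$species$kind == "indicator"]
    if (!all(state[ind] %in% c(0, 1)) || sum(state[ind]) != 1) {
      stop("promoter indicators are not one-hot")
    }
    if (any(state < 0)) stop("negative copy number")
  }
  invisible(TRUE)
}

#' Default initial state of a built-in model
#'
#' Empty promoter (`S0 = 1`), no mRNA, no protein.
#'
#' @param network A `reaction_network`.
#' @return Named numeric vector over all species.
#' @export
default_init <- function(network) {
  s <- setNames(numeric(nrow(network$species)), network$species$name)
  s["S0"] <- 1
  s
}

#' @exportS3Method base::print
print.reaction_network <- function(x, ...) {
  n1 <- sum(vapply(x$reactions, function(r) r$group == "G1", logical(1)))
  cat("<reaction_network> model:", x$model,
      "|", nrow(x$species), "species |",
      length(x$reactions), "reactions (", n1, "G1 )\n")
  invisible(x)
}

## Internal: (c, d) coefficients of each G1 reaction's propensity as a linear
## function a_mu = c_mu + d_mu * n_free of the single G2 species that enters
## G1 propensities (n for the switch, nd for the Griffith model), at a fixed
## G1 state.  Exact because mass-action propensities here are linear in that
## species.
g1_linear_coefs <- function(network, g1_state) {
  free <- if (network$model == "switch") "n" else paste0("n", network$d)
  s0 <- s1 <- setNames(numeric(nrow(network$species)), network$species$name)
  s0[names(g1_state)] <- g1_state
  s1 <- s0
  s1[free] <- 1
  a0 <- propensities(network, s0, group = "G1")
  a1 <- propensities(network, s1, group = "G1")
  list(c = a0, d = a1 - a0)
}
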