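#' Default rate constants for the genetic switch
#'
#' Rate constants, in inverse minutes, for the positively autoregulated
#' single-gene switch with promoter cooperativity 2. The promoter has three
#' occupancy states (`S0` empty, `S1` one protein bound, `S2` two bound);
#' transcription is weak (`r0`) unless the promoter is doubly occupied (`r`).
#'
#' @param alpha1,alpha2 protein-promoter binding frequencies (per protein per
#'   minute) for the first and second binding step.
#' @param beta1,beta2 unbinding frequencies (per minute).
#' @param r0 basal transcription frequency (per minute).
#' @param r activated transcription frequency (per minute).
#' @param K translation frequency per mRNA (per minute).
#' @param k mRNA degradation frequency per molecule (per minute).
#' @param q protein degradation frequency per molecule (per minute).
#' @return Named list of rates.
#' @examples
#' switch_params()            # defaults
#' switch_params(r = 20)      # override one rate
#' @export
switch_params <- function(alpha1 = 0.001, alpha2 = 0.001, beta1 = 1, beta2 = 1,
                          r0 = 0.1, r = 10, K = 1, k = 0.05, q = 0.01) {
  p <- list(alpha1 = alpha1, alpha2 = alpha2, beta1 = beta1, beta2 = beta2,
            r0 = r0, r = r, K = K, k = k, q = q)
  check_rates(p)
  p
}

#' Default rate constants for the Griffith oscillator
#'
#' Rate constants, in inverse minutes, for the Griffith-type genetic
#' oscillator: a promoter with five occupancy states (`S0` ... `S4`) repressed
#' by the mature protein conformation, an mRNA, and a protein passing through
#' `d` conformations (`n1` ... `nd`) before the mature form `nd` can bind the
#' promoter.
#'
#' @param alpha1,alpha2,alpha3,alpha4 binding frequencies of the mature
#'   protein to the four promoter occupancy transitions (per protein per
#'   minute).
#' @param beta1,beta2,beta3,beta4 unbinding frequencies (per minute).
#' @param r transcription frequency from the unrepressed promoter (per
#'   minute).
#' @param K translation frequency per mRNA (per minute).
#' @param k mRNA degradation frequency (per minute).
#' @param q mature-protein degradation frequency (per minute).
#' @param a conformation conversion frequency (per minute).
#' @return Named list of rates.
#' @export
griffith_params <- function(alpha1 = 0.01, alpha2 = 0.01, alpha3 = 0.01,
                            alpha4 = 0.01, beta1 = 1, beta2 = 1, beta3 = 1,
                            beta4 = 1, r = 10, K = 1, k = 0.05, q = 0.05,
                            a = 0.1) {
  p <- list(alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
            alpha4 = alpha4, beta1 = beta1, beta2 = beta2, beta3 = beta3,
            beta4 = beta4, r = r, K = K, k = k, q = q, a = a)
  check_rates(p)
  p
}

check_rates <- function(p) {
  bad <- vapply(p, function(x) !is.numeric(x) || length(x) != 1L ||
                  !is.finite(x) || x <= 0, logical(1))
  if (any(bad)) {
    stop("rate constants must be single positive numbers; offending: ",
         paste(names(p)[bad], collapse = ", "), call. = FALSE)
  }
  invisible(p)
}
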