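# Shannon-level baselines. All logarithms base 2; results in bits.

#' Shannon entropy of a discrete distribution
#'
#' @param p Numeric probability vector (must sum to 1 within 1e-9).
#' @return Entropy in bits, with `0 * log2(0) := 0`.
#' @examples
#' entropy_bits(rep(1 / 8, 8)) # 3
#' @export
entropy_bits <- function(p) {
  p <- check_dist(p)
  pos <- p > 0
  -sum(p[pos] * log2(p[pos]))
}

#' Kullback-Leibler divergence between two distributions
#'
#' @param p,q Numeric probability vectors over the same ordered support.
#' @return `sum(p * log2(p / q))` in bits. Infinite (with a warning) when `q`
#'   is zero somewhere `p` is positive.
#' @examples
#' kld_bits(c(0.75, 0.25), c(0.5, 0.5)) # 0.18872...
#' @export
kld_bits <- function(p, q) {
  p <- check_dist(p)
  q <- check_dist(q)
  stopifnot(length(p) == length(q))
  pos <- p > 0
  if (any(q[pos] == 0)) {
    warning("infinite divergence: q has zero mass where p is positive")
    return(Inf)
  }
  sum(p[pos] * log2(p[pos] / q[pos]))
}

check_dist <- function(p, tol = 1e-9) {
  p <- as.numeric(p)
  if (any(p < -TOL_CLIP)) stop("negative probabilities")
  p <- pmax(p, 0)
  if (abs(sum(p) - 1) > tol) stop("distribution does not sum to 1")
  p
}

#' Predictive information of a TPM under a prior over states
#'
#' The mutual information `I(V_{t-1}; V_t)` between consecutive system
#' states, computed as the prior-weighted average Kullback-Leibler divergence
#' of each transition row from the prior-weighted mixture of rows.
#'
#' @param x A `tpm` object.
#' @param prior Numeric probability vector over the `2^n` prior states;
#'   defaults to uniform (in which case the value equals
#'   [effective_information()]).
#' @return Mutual information in bits.
#' @examples
#' predictive_information(fixture_tpm("mcx")) # 2.5
#' @export
predictive_information <- function(x, prior = NULL) {
  stopifnot(inherits(x, "tpm"))
  sbs <- x$state_by_state
  N <- nrow(sbs)
  if (is.null(prior)) prior <- rep(1 / N, N)
  prior <- check_dist(prior)
  stopifnot(length(prior) == N)
  mix <- as.numeric(prior %*% sbs)
  total <- 0
  for (r in which(prior > 0)) {
    p <- sbs[r, ]
    pos <- p > 0
    total <- total + prior[r] * sum(p[pos] * log2(p[pos] / mix[pos]))
  }
  total
}

#' Effective information of a TPM
#'
#' Predictive information under an imposed uniform (maximum-entropy) prior
#' over prior states: the average divergence of each row of the TPM from the
#' unweighted mixture of all rows. Because the uniform prior corresponds to
#' perturbing the system into every state, this is a causal rather than an
#' observational measure; it is maximal at `n` bits exactly for reversible
#' (permutation) systems.
#'
#' @param x A `tpm` object.
#' @return Effective information in bits, in `[0, n]`.
#' @examples
#' effective_information(fixture_tpm("mcx")) # 2.5
#' effective_information(fixture_tpm("shift3")) # 3
#' @export
effective_information <- function(x) {
  predictive_information(x, prior = NULL)
}
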