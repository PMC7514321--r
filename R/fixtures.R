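# Reference systems used throughout the documentation and tests.

#' Node mechanisms of the MCX example system
#'
#' The three-node logic-gate circuit used as the running example: M turns on
#' when at least two of (M, C, X) were on (majority), C copies M, and X is
#' the exclusive-or of M and C. Deterministic, not reversible (two states map
#' to 000), with effective information 2.5 bits.
#'
#' @return A named list of mechanism functions suitable for [build_tpm()].
#' @export
mcx_mechanisms <- function() {
  list(
    M = function(s) as.numeric(sum(s) >= 2),
    C = function(s) s[1],
    X = function(s) as.numeric(xor(s[1] == 1, s[2] == 1))
  )
}

#' Built-in example systems
#'
#' @param name One of:
#'   * `"mcx"` — the majority/copy/xor circuit ([mcx_mechanisms()]);
#'   * `"identity3"` — the 3-node identity permutation (8 fixed points);
#'   * `"shift3"` — a single 8-cycle through the state space in index order,
#'     an ergodic-reversible system.
#' @return A `tpm` object.
#' @examples
#' fixture_tpm("mcx")
#' @export
fixture_tpm <- function(name = c("mcx", "identity3", "shift3")) {
  name <- match.arg(name)
  switch(name,
    mcx = build_tpm(mcx_mechanisms()),
    identity3 = tpm_from_permutation(1:8),
    shift3 = tpm_from_permutation(c(2:8, 1L))
  )
}
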