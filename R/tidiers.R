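# broom-style tidiers for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and summarise composition results
#'
#' `tidy()` returns the long per-subset table (one row per subset and
#' direction); `glance()` a one-row summary with the phi sums.
#'
#' @param x A `composition` object.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.composition <- function(x, ...) {
  x$table
}

#' @rdname tidy.composition
#' @exportS3Method generics::glance
glance.composition <- function(x, ...) {
  tibble::tibble(
    state = x$state_label,
    n_subsets = length(unique(x$table$subset)),
    sum_phi_c = x$sum_phi_c,
    sum_phi_e = x$sum_phi_e,
    total = x$total
  )
}

#' Tidy and summarise big-phi results
#'
#' `tidy()` returns the per-subset delta-phi table under the minimizing cut;
#' `glance()` a one-row summary (big phi, minimizing cut and side, intact
#' sums).
#'
#' @param x A `big_phi_result` object.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.big_phi_result <- function(x, ...) {
  x$delta_table
}

#' @rdname tidy.big_phi_result
#' @exportS3Method generics::glance
glance.big_phi_result <- function(x, ...) {
  tibble::tibble(
    state = x$state_label,
    big_phi = x$big_phi,
    cut = x$cut_label,
    side = x$side,
    sum_phi_c = x$composition$sum_phi_c,
    sum_phi_e = x$composition$sum_phi_e
  )
}

#' Tidy a phi result
#'
#' @param x A `phi_result` object.
#' @param ... Unused.
#' @return A one-row tibble with the mechanism, direction, phi and MIP.
#' @exportS3Method generics::tidy
tidy.phi_result <- function(x, ...) {
  tibble::tibble(
    mechanism = paste(x$mechanism_labels, collapse = ""),
    mech_state = state_label(x$mech_state),
    direction = x$direction,
    phi = x$phi,
    mip = format_partition(x$mip, x$node_labels),
    effective_purview = paste(x$effective_purview_labels, collapse = ","),
    undefined = x$undefined
  )
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
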