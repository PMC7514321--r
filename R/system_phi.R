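# System-level integration: unidirectional cuts, re-evaluation of every
# irreducible subset inside the cut system, and compositional big phi.
#
# A cut X -/-> S\X severs all connections from source part X into the rest:
# every node outside X receives independent maximum-entropy noise on its
# inputs from X (its on-probability is averaged uniformly over the states of
# the X nodes). One cut TPM serves both the cause and the effect side, since
# the partitioned system is a single modified network within which both
# repertoire directions are computed.

#' Apply a unidirectional system cut to a TPM
#'
#' @param x A `tpm` object (state-by-node form required).
#' @param source Non-empty proper subset of nodes (labels or indices): the
#'   part whose outgoing connections are severed.
#' @return A `tpm` in which each node outside `source` has its on-probability
#'   averaged uniformly over all states of the `source` nodes; nodes in
#'   `source` keep their mechanisms. The result is row-stochastic and
#'   conditionally independent by construction.
#' @examples
#' mcx <- fixture_tpm("mcx")
#' state_by_node(apply_cut(mcx, "X")) # M loses its X input
#' @export
apply_cut <- function(x, source) {
  stopifnot(inherits(x, "tpm"))
  n <- x$n_nodes
  src <- sort(resolve_nodes(source, x$node_labels))
  if (length(src) == 0 || length(src) >= n) {
    stop("cut source must be a non-empty proper subset of the nodes")
  }
  sbn <- x$state_by_node
  if (is.null(sbn)) {
    stop("system cuts require a conditionally independent TPM")
  }
  B <- state_grid(n)
  keep <- setdiff(seq_len(n), src)
  # group prior states by their non-source coordinates and average
  grp <- state_index(B[, keep, drop = FALSE])
  new_sbn <- sbn
  for (j in keep) {
    means <- as.numeric(rowsum(sbn[, j], grp)) / 2L^length(src)
    new_sbn[, j] <- means[grp]
  }
  mechs <- lapply(seq_len(n), function(i) new_sbn[, i])
  names(mechs) <- x$node_labels
  build_tpm(mechs)
}

#' Enumerate all unidirectional system cuts
#'
#' @param x A `tpm` object or a node count.
#' @return A list of integer vectors, the `2^n - 2` cut sources, ordered by
#'   size then lexicographically.
#' @export
system_cuts <- function(x) {
  n <- if (inherits(x, "tpm")) x$n_nodes else as.integer(x)
  subs <- subset_order(n)
  subs[lengths(subs) < n]
}

#' Phi of a mechanism inside a cut system
#'
#' Re-evaluates the irreducible cause or effect information of a mechanism
#' after a unidirectional system cut, with the minimum-information-partition
#' search re-run from scratch inside the cut system.
#'
#' @inheritParams mechanism_phi
#' @param cut Cut source nodes (labels or indices), or a `tpm` already cut.
#' @return A `phi_result` computed on the cut TPM.
#' @examples
#' mcx <- fixture_tpm("mcx")
#' phi_under_cut(mcx, "X", "X", 1, "effect")$phi # 0: X no longer constrains
#' @export
phi_under_cut <- function(x, cut, mechanism, mech_state,
                          direction = c("cause", "effect")) {
  direction <- match.arg(direction)
  cut_tpm <- if (inherits(cut, "tpm")) cut else apply_cut(x, cut)
  mechanism_phi(cut_tpm, mechanism, mech_state, direction)
}

#' Compositional system-level integrated information
#'
#' For every unidirectional cut, every subset with positive intact phi is
#' re-evaluated in the cut system; the per-subset losses are summed
#' separately over the cause and effect side, and big phi is the minimum
#' over cuts of the smaller of the two sums. A system with big phi = 0 is
#' reducible: some cut severs nothing that any subset irreducibly specifies.
#'
#' Two accounting rules for the per-subset loss are provided. The default,
#' `delta = "concept"`, treats a mechanism's constraint as identified by its
#' effective purview (the nodes it actually constrains): if the cut changes
#' that purview, the intact constraint no longer exists in the cut system
#' and its full phi counts as lost, `delta phi = phi`; if the purview is
#' unchanged, the loss is the difference `phi - phi_cut`. `delta = "plain"`
#' always uses the raw difference regardless of purview identity. The
#' concept rule guarantees `big phi <= min(sum phiC, sum phiE)`; under
#' either rule, negative same-purview differences (possible because the
#' partition search is re-minimised inside the cut system) are kept as
#' computed and reported via a warning.
#'
#' @param x A `tpm` object.
#' @param state Current system state (0/1 vector or bit string).
#' @param comp Optionally, a precomputed [composition()] of `x` at `state`
#'   to reuse.
#' @param delta Loss accounting rule, `"concept"` (default) or `"plain"`;
#'   see Details.
#' @return A `big_phi_result`: `big_phi` (bits), `cut` (minimizing source
#'   nodes), `side` (`"cause"` or `"effect"`), `delta_table` (per-subset
#'   deltas under the minimizing cut), `cut_summary` (per-cut sums), and the
#'   intact `composition`.
#' @examples
#' res <- big_phi(fixture_tpm("mcx"), "011")
#' res$big_phi # 1.019
#' @export
big_phi <- function(x, state, comp = NULL, delta = c("concept", "plain")) {
  stopifnot(inherits(x, "tpm"))
  delta <- match.arg(delta)
  bits <- parse_state(state)
  stopifnot(length(bits) == x$n_nodes)
  comp <- comp %||% composition(x, bits)
  active <- comp$table[comp$table$phi > PHI_TOL, , drop = FALSE]
  intact_purview <- lapply(seq_len(nrow(active)), function(k) {
    key <- paste0(active$direction[k], "|",
                  paste(active$nodes[[k]], collapse = ","))
    comp$results[[key]]$effective_purview
  })
  cuts <- system_cuts(x)
  cut_rows <- list()
  delta_tabs <- vector("list", length(cuts))
  for (ci in seq_along(cuts)) {
    src <- cuts[[ci]]
    cut_tpm <- apply_cut(x, src)
    cut_ctx <- tpm_ctx(cut_tpm)
    deltas <- numeric(nrow(active))
    phi_cut <- numeric(nrow(active))
    survives <- logical(nrow(active))
    for (k in seq_len(nrow(active))) {
      nodes <- active$nodes[[k]]
      r <- ctx_phi(cut_ctx, nodes, bits[nodes], active$direction[k])
      phi_cut[k] <- r$phi
      survives[k] <- identical(r$effective_purview, intact_purview[[k]])
      deltas[k] <- if (delta == "plain" || survives[k]) {
        active$phi[k] - r$phi
      } else {
        active$phi[k]
      }
    }
    if (any(deltas < -PHI_TOL)) {
      warning(sprintf(
        "negative delta phi under cut {%s} (partition re-minimised in the cut system)",
        paste(x$node_labels[src], collapse = ",")
      ))
    }
    sum_c <- sum(deltas[active$direction == "cause"])
    sum_e <- sum(deltas[active$direction == "effect"])
    delta_tabs[[ci]] <- tibble::tibble(
      subset = active$subset,
      nodes = active$nodes,
      subset_state = active$subset_state,
      direction = active$direction,
      phi = active$phi,
      phi_cut = phi_cut,
      purview_unchanged = survives,
      delta_phi = deltas
    )
    cut_rows[[ci]] <- tibble::tibble(
      cut = paste(x$node_labels[src], collapse = ""),
      cut_nodes = list(src),
      sum_delta_phi_c = sum_c,
      sum_delta_phi_e = sum_e,
      loss = min(sum_c, sum_e),
      side = if (sum_e <= sum_c) "effect" else "cause"
    )
  }
  cut_summary <- dplyr::bind_rows(cut_rows)
  best <- which.min(cut_summary$loss) # first minimum: enumeration-order ties
  structure(
    list(
      state = bits,
      state_label = state_label(bits),
      node_labels = x$node_labels,
      big_phi = max(cut_summary$loss[best], 0),
      cut = cuts[[best]],
      cut_label = cut_summary$cut[best],
      side = cut_summary$side[best],
      delta_table = delta_tabs[[best]],
      cut_summary = cut_summary,
      composition = comp
    ),
    class = "big_phi_result"
  )
}

#' @export
print.big_phi_result <- function(x, ...) {
  cat(sprintf(
    "<big phi> state %s: %.4g bits (cut {%s} -/-> rest, %s side)\n",
    x$state_label, x$big_phi, x$cut_label, x$side
  ))
  cat(sprintf("intact sums: sum(phiC) = %.4g, sum(phiE) = %.4g\n",
              x$composition$sum_phi_c, x$composition$sum_phi_e))
  invisible(x)
}

#' State-averaged big phi
#'
#' `big_phi_by_state()` evaluates [big_phi()] in every one of the `2^n`
#' system states; `mean_big_phi()` returns the unweighted average, the
#' state-independent summary used when comparing systems.
#'
#' @param x A `tpm` object.
#' @return `big_phi_by_state()`: a tibble with one row per state (`state`,
#'   `big_phi`, `sum_phi_c`, `sum_phi_e`, `cut`, `side`);
#'   `mean_big_phi()`: a single number in bits.
#' @export
big_phi_by_state <- function(x) {
  stopifnot(inherits(x, "tpm"))
  B <- state_grid(x$n_nodes)
  rows <- lapply(seq_len(nrow(B)), function(r) {
    res <- big_phi(x, B[r, ])
    tibble::tibble(
      state = state_label(B[r, ]),
      big_phi = res$big_phi,
      sum_phi_c = res$composition$sum_phi_c,
      sum_phi_e = res$composition$sum_phi_e,
      cut = res$cut_label,
      side = res$side
    )
  })
  dplyr::bind_rows(rows)
}

#' @rdname big_phi_by_state
#' @export
mean_big_phi <- function(x) {
  mean(big_phi_by_state(x)$big_phi)
}
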