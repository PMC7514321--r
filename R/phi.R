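# Irreducible cause/effect information of a mechanism: enumerate permissible
# subset partitions, build partitioned repertoires, minimise the divergence
# over partitions (minimum information partition, MIP).
#
# A partition splits the mechanism into m >= 2 non-empty parts and assigns
# each purview node to exactly one part or to a "leftover" set that is left
# unconstrained. Mechanism parts must be non-empty; purview parts may be
# empty. The purview of a phi evaluation is the full node set: with a KLD
# difference measure, unconstrained purview nodes contribute nothing, so the
# full purview attains the maximal value and no purview search is needed.

PHI_TOL <- 1e-9

# ---- set partitions of the mechanism ---------------------------------------

# all partitions of seq_len(k) into >= 2 blocks, restricted-growth-string
# order; blocks ordered by smallest contained element
set_partitions <- function(k) {
  if (k < 2) return(list())
  out <- list()
  rgs <- integer(k)
  recurse <- function(pos, maxused) {
    if (pos > k) {
      if (maxused >= 2L) {
        blocks <- split(seq_len(k), rgs)
        out[[length(out) + 1L]] <<- unname(blocks)
      }
      return(invisible())
    }
    for (b in seq_len(maxused + 1L)) {
      rgs[pos] <<- b
      recurse(pos + 1L, max(maxused, b))
    }
    rgs[pos] <<- 0L
  }
  rgs[1] <- 1L
  recurse(2L, 1L)
  out
}

#' Enumerate permissible partitions of a mechanism and its purview
#'
#' Generates every partition of the mechanism into at least two non-empty
#' parts, crossed with every assignment of each purview node to exactly one
#' part or to the leftover set (rendered unconstrained under the partition).
#' Enumeration order is deterministic: set partitions of the mechanism in
#' restricted-growth order with parts ordered by smallest contained node,
#' then purview assignments in lexicographic order with the first purview
#' node varying fastest.
#'
#' @param mechanism Integer node indices of the mechanism (length >= 2).
#' @param purview Integer node indices of the purview (may be empty).
#' @return A list of partitions; each is a list with `parts` (a list of
#'   `list(mech =, purview =)` index vectors) and `leftover` (purview nodes
#'   assigned to no part).
#' @examples
#' length(enumerate_partitions(c(1, 2), c(1, 2, 3))) # 27
#' @export
enumerate_partitions <- function(mechanism, purview) {
  mechanism <- sort(as.integer(mechanism))
  purview <- sort(as.integer(purview))
  if (length(mechanism) < 2) {
    stop("singleton mechanisms are not partitioned; use the single-node path")
  }
  key <- paste0(paste(mechanism, collapse = ","), "|",
                paste(purview, collapse = ","))
  hit <- .partition_memo[[key]]
  if (!is.null(hit)) return(hit)
  p <- length(purview)
  out <- list()
  for (blocks in set_partitions(length(mechanism))) {
    m <- length(blocks)
    n_assign <- (m + 1L)^p
    for (a in seq_len(n_assign) - 1L) {
      assign <- integer(p)
      rem <- a
      for (j in seq_len(p)) { # first purview node varies fastest
        assign[j] <- rem %% (m + 1L)
        rem <- rem %/% (m + 1L)
      }
      parts <- lapply(seq_len(m), function(b) {
        list(
          mech = mechanism[blocks[[b]]],
          purview = purview[assign == b]
        )
      })
      out[[length(out) + 1L]] <- list(
        parts = parts,
        leftover = purview[assign == 0L]
      )
    }
  }
  .partition_memo[[key]] <- out
  out
}

.partition_memo <- new.env(parent = emptyenv())

# ---- partitioned repertoires -----------------------------------------------

# distribution over `purview` states under partition psi (internal, ctx-based)
ctx_partitioned <- function(ctx, mstate_by_node, psi, purview, direction) {
  full <- rep(1, 2L^length(purview))
  for (part in psi$parts) {
    Zj <- part$purview
    if (length(Zj) == 0) next # pi(empty | x_j) = 1
    xs <- mstate_by_node[as.character(part$mech)]
    d <- if (direction == "effect") {
      ctx_effect_repertoire(ctx, part$mech, xs, Zj)
    } else {
      ctx_cause_repertoire(ctx, part$mech, xs, Zj)
    }
    if (is_undefined(d)) return(structure(full, undefined = TRUE))
    full <- full * expand_onto(ctx, d, Zj, purview)
  }
  if (length(psi$leftover)) {
    d <- ctx_unconstrained(ctx, direction, psi$leftover)
    full <- full * expand_onto(ctx, d, psi$leftover, purview)
  }
  full
}

#' Repertoire of a mechanism under a subset partition
#'
#' Applies a partition from [enumerate_partitions()] to a mechanism: the
#' result is the product of the part repertoires (each part's mechanism
#' constraining only its own purview nodes) times the unconstrained
#' repertoire of the leftover purview nodes. Joint constraints across parts
#' are thereby eliminated.
#'
#' @inheritParams effect_repertoire
#' @param psi A partition as returned by [enumerate_partitions()].
#' @param direction `"cause"` or `"effect"`.
#' @return A `repertoire` object over the purview.
#' @export
partitioned_repertoire <- function(x, mechanism, mech_state, purview, psi,
                                   direction = c("cause", "effect")) {
  direction <- match.arg(direction)
  ctx <- if (inherits(x, "tpm")) tpm_ctx(x) else x
  m <- resolve_mech_ctx(ctx, mechanism, mech_state)
  Z <- sort(resolve_nodes(purview, ctx$node_labels))
  mstate_by_node <- stats::setNames(m$state, as.character(m$nodes))
  dist <- ctx_partitioned(ctx, mstate_by_node, psi, Z, direction)
  if (is_undefined(dist)) {
    stop("a part of the partition has an undefined cause repertoire")
  }
  new_repertoire(dist, direction, Z, ctx$node_labels, m$nodes, m$state)
}

# ---- phi -------------------------------------------------------------------

new_phi_result <- function(mechanism, mech_state, labels, direction, phi,
                           mip, mips, repertoire, partitioned,
                           effective_purview, undefined = FALSE) {
  structure(
    list(
      mechanism = mechanism,
      node_labels = labels,
      mechanism_labels = labels[mechanism],
      mech_state = mech_state,
      direction = direction,
      phi = phi,
      mip = mip,
      co_minimal = mips,
      repertoire = repertoire,
      partitioned_repertoire = partitioned,
      effective_purview = effective_purview,
      effective_purview_labels = labels[effective_purview],
      undefined = undefined
    ),
    class = "phi_result"
  )
}

#' @export
print.phi_result <- function(x, ...) {
  cat(sprintf(
    "<phi> %s(%s = %s) = %.4g bits%s\n",
    if (x$direction == "cause") "phiC" else "phiE",
    paste(x$mechanism_labels, collapse = ""),
    state_label(x$mech_state), x$phi,
    if (x$undefined) " [undefined cause repertoire]" else ""
  ))
  if (!is.null(x$mip)) {
    cat("MIP:", format_partition(x$mip, x$node_labels), "\n")
  }
  if (length(x$effective_purview)) {
    cat("effective purview:",
        paste(x$effective_purview_labels, collapse = ","), "\n")
  }
  invisible(x)
}

format_partition <- function(psi, labels, ...) {
  if (is.null(psi)) return("none")
  parts <- vapply(psi$parts, function(p) {
    sprintf("(%s|%s)",
            if (length(p$purview)) paste(labels[p$purview], collapse = "")
            else "0",
            paste(labels[p$mech], collapse = ""))
  }, character(1))
  s <- paste(parts, collapse = " x ")
  if (length(psi$leftover)) {
    s <- paste0(s, " [", paste(labels[psi$leftover], collapse = ""),
                " unconstrained]")
  }
  s
}

# core phi computation on a prepared context; mech sorted ascending
ctx_phi <- function(ctx, mech, mstate, direction, all_mips = FALSE) {
  n <- ctx$n
  purview <- seq_len(n)
  intact <- if (direction == "effect") {
    ctx_effect_repertoire(ctx, mech, mstate, purview)
  } else {
    ctx_cause_repertoire(ctx, mech, mstate, purview)
  }
  labels <- ctx$node_labels
  uncon <- ctx_unconstrained(ctx, direction, purview)
  if (is_undefined(intact)) {
    warning("undefined cause repertoire; phi set to 0")
    return(new_phi_result(mech, mstate, labels, direction, 0, NULL, list(),
                          NULL, NULL, integer(0), undefined = TRUE))
  }
  rep_obj <- new_repertoire(intact, direction, purview, labels, mech, mstate)
  # nodes whose constrained marginal differs from the unconstrained one
  eff <- purview[vapply(purview, function(z) {
    max(abs(marginal_onto(ctx, intact, z) -
              marginal_onto(ctx, uncon, z))) > PHI_TOL
  }, logical(1))]
  if (length(mech) == 1) {
    phi <- kld_strict(intact, uncon)
    part_obj <- new_repertoire(uncon, direction, purview, labels,
                               integer(0), integer(0))
    return(new_phi_result(mech, mstate, labels, direction, phi, NULL, list(),
                          rep_obj, part_obj, eff))
  }
  mstate_by_node <- stats::setNames(mstate, as.character(mech))
  best <- Inf
  best_psi <- NULL
  best_dist <- NULL
  mips <- list()
  for (psi in enumerate_partitions(mech, purview)) {
    d <- ctx_partitioned(ctx, mstate_by_node, psi, purview, direction)
    if (is_undefined(d)) next # cannot occur when the intact repertoire exists
    val <- kld_strict(intact, d)
    if (val < best - PHI_TOL) {
      best <- val
      best_psi <- psi
      best_dist <- d
      mips <- list(psi)
    } else if (all_mips && abs(val - best) <= PHI_TOL) {
      mips[[length(mips) + 1L]] <- psi
    }
  }
  phi <- if (best < PHI_TOL) 0 else best
  part_obj <- new_repertoire(best_dist, direction, purview, labels,
                             mech, mstate)
  new_phi_result(mech, mstate, labels, direction, phi, best_psi,
                 if (all_mips) mips else list(best_psi), rep_obj, part_obj,
                 eff)
}

# KLD for phi searches: the partitioned repertoire's support must contain the
# intact repertoire's support; a violation indicates a broken invariant.
kld_strict <- function(p, q) {
  pos <- p > 0
  if (any(q[pos] <= 0)) {
    stop("partitioned repertoire lacks support where the intact repertoire ",
         "has mass; repertoire invariant violated")
  }
  sum(p[pos] * log2(p[pos] / q[pos]))
}

#' Irreducible cause or effect information of a mechanism
#'
#' Computes phi of a mechanism in its current state over the full purview:
#' the Kullback-Leibler divergence between the intact repertoire and the
#' repertoire under the minimum information partition (MIP). Mechanisms of a
#' single node cannot be partitioned; their phi is the divergence from the
#' unconstrained repertoire (the total intrinsic information they specify).
#' Ties between co-minimal partitions are broken by enumeration order; set
#' `all_mips = TRUE` to retrieve every co-minimal partition.
#'
#' @inheritParams effect_repertoire
#' @param direction `"cause"` or `"effect"`.
#' @param all_mips Record all co-minimal partitions?
#' @return A `phi_result` with elements `phi` (bits), `mip`, `repertoire`,
#'   `partitioned_repertoire`, `effective_purview`, and `undefined`.
#' @examples
#' mcx <- fixture_tpm("mcx")
#' mechanism_phi(mcx, c("M", "X"), c(0, 1), "cause")$phi # 0.415
#' @export
mechanism_phi <- function(x, mechanism, mech_state,
                          direction = c("cause", "effect"),
                          all_mips = FALSE) {
  direction <- match.arg(direction)
  ctx <- if (inherits(x, "tpm")) tpm_ctx(x) else x
  m <- resolve_mech_ctx(ctx, mechanism, mech_state)
  if (length(m$nodes) == 0) stop("mechanism must be non-empty")
  ctx_phi(ctx, m$nodes, m$state, direction, all_mips)
}

# ---- composition ------------------------------------------------------------

# non-empty subsets ordered by size then lexicographically by node indices
subset_order <- function(n) {
  subs <- lapply(seq_len(2L^n - 1L), function(mask) {
    which(bitwAnd(bitwShiftR(mask, 0:(n - 1L)), 1L) == 1L)
  })
  subs[order(lengths(subs), vapply(subs, paste, character(1), collapse = ","))]
}

#' Causal composition of a system state
#'
#' Evaluates the irreducible cause and effect information of every non-empty
#' subset of system nodes in the given state, and totals them. The sums over
#' subsets, `sum(phiC)`, `sum(phiE)` and their grand total, quantify the
#' compositional intrinsic information the system specifies about its own
#' prior and next states.
#'
#' @param x A `tpm` object.
#' @param state Current system state: 0/1 vector or bit string such as
#'   `"011"` (positional, first character = first node).
#' @return A `composition` object: a list with `table` (tibble of per-subset
#'   phi values), `results` (the underlying `phi_result` objects),
#'   `sum_phi_c`, `sum_phi_e`, `total`, `state`. Use [tidy()] / [glance()]
#'   for tabular access and [write_composition()] to export.
#' @examples
#' comp <- composition(fixture_tpm("mcx"), "011")
#' glance(comp) # sums: 5.415, 3.397, 8.812
#' @export
composition <- function(x, state) {
  stopifnot(inherits(x, "tpm"))
  bits <- parse_state(state)
  stopifnot(length(bits) == x$n_nodes)
  ctx <- tpm_ctx(x)
  subs <- subset_order(x$n_nodes)
  results <- list()
  rows <- list()
  for (s in subs) {
    for (direction in c("cause", "effect")) {
      r <- ctx_phi(ctx, s, bits[s], direction)
      key <- paste0(direction, "|", paste(s, collapse = ","))
      results[[key]] <- r
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subset = paste(x$node_labels[s], collapse = ""),
        nodes = list(s),
        subset_state = state_label(bits[s]),
        order = length(s),
        direction = direction,
        phi = r$phi,
        mip = format_partition(r$mip, x$node_labels),
        effective_purview = paste(r$effective_purview_labels, collapse = ","),
        undefined = r$undefined
      )
    }
  }
  tab <- dplyr::bind_rows(rows)
  sum_c <- sum(tab$phi[tab$direction == "cause"])
  sum_e <- sum(tab$phi[tab$direction == "effect"])
  structure(
    list(
      table = tab,
      results = results,
      state = bits,
      state_label = state_label(bits),
      node_labels = x$node_labels,
      sum_phi_c = sum_c,
      sum_phi_e = sum_e,
      total = sum_c + sum_e
    ),
    class = "composition"
  )
}

#' @export
print.composition <- function(x, ...) {
  cat(sprintf(
    "<composition> state %s: sum(phiC) = %.4g, sum(phiE) = %.4g, total = %.4g bits\n",
    x$state_label, x$sum_phi_c, x$sum_phi_e, x$total
  ))
  wide <- tidyr_pivot(x$table)
  print(as.data.frame(wide))
  invisible(x)
}

# minimal wide view without a tidyr dependency: subsets as columns
tidyr_pivot <- function(tab) {
  subsets <- unique(tab$subset)
  out <- data.frame(row.names = c("phiC", "phiE"))
  for (s in subsets) {
    out[[s]] <- c(
      round(tab$phi[tab$subset == s & tab$direction == "cause"], 3),
      round(tab$phi[tab$subset == s & tab$direction == "effect"], 3)
    )
  }
  out
}
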