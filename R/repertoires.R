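# Cause and effect repertoires with interventionist semantics.
#
# Effect repertoire of a mechanism subset X in state x over purview Z at t+1:
# product over purview nodes of the node's on-probability averaged uniformly
# over all completions of the non-mechanism nodes (virtual independent noise
# inputs, discounting common-input correlations).
#
# Cause repertoire over Z at t-1: per mechanism *element*, Bayesian inversion
# of the element's conditional under a uniform prior over the full prior
# state space, marginalized onto Z; the per-element repertoires are then
# multiplied and renormalized. The uniform prior is fixed: the causal
# semantics require maximum-entropy perturbation, not an observed prior.

# ---- internal computation context ------------------------------------------

# Precomputed quantities for repertoire algebra on one TPM. `cache` memoises
# repertoires across the many partition evaluations of a phi search.
tpm_ctx <- function(x) {
  stopifnot(inherits(x, "tpm"))
  if (is.null(x$state_by_node)) {
    stop(
      "repertoire analysis requires a conditionally independent TPM ",
      "(state-by-node form); this TPM is state-by-state only"
    )
  }
  n <- x$n_nodes
  sbn <- x$state_by_node
  N <- nrow(sbn)
  B <- state_grid(n)
  # q[[i]][[b+1]]: normalized distribution over prior states v proportional
  # to p(node i in state b at t | do(v)); NULL when the state is unreachable
  q <- lapply(seq_len(n), function(i) {
    lapply(c(0L, 1L), function(b) {
      w <- if (b == 1L) sbn[, i] else 1 - sbn[, i]
      s <- sum(w)
      if (s == 0) NULL else w / s
    })
  })
  env <- new.env(parent = emptyenv())
  list(
    n = n, N = N, B = B, sbn = sbn,
    node_labels = x$node_labels,
    uncon_on = colMeans(sbn), # unconstrained per-node on-probability
    q = q, cache = env
  )
}

# rows of the full state space consistent with a partial assignment
consistent_rows <- function(ctx, nodes, values) {
  if (length(nodes) == 0) return(seq_len(ctx$N))
  sel <- rep(TRUE, ctx$N)
  for (k in seq_along(nodes)) sel <- sel & (ctx$B[, nodes[k]] == values[k])
  which(sel)
}

# marginalize a distribution over the full state space onto node subset Z
marginal_onto <- function(ctx, dist, Z) {
  idx <- state_index(ctx$B[, Z, drop = FALSE])
  out <- numeric(2L^length(Z))
  out[sort(unique(idx))] <- as.numeric(rowsum(dist, idx))
  out
}

# expand a distribution over subset Z to a factor over the full purview P
# (constant in the remaining coordinates)
expand_onto <- function(ctx, dist, Z, P) {
  BP <- state_grid(length(P))
  pos <- match(Z, P)
  idx <- state_index(BP[, pos, drop = FALSE])
  dist[idx]
}

# Bernoulli product over purview nodes -> distribution, little-endian in Z
bernoulli_product <- function(on_probs) {
  out <- 1
  for (p in on_probs) out <- c(out * (1 - p), out * p)
  out
}

# effect marginal of purview node `node` given mechanism (nodes, values)
effect_marginal <- function(ctx, mech, mstate, node) {
  rows <- consistent_rows(ctx, mech, mstate)
  mean(ctx$sbn[rows, node])
}

ctx_effect_repertoire <- function(ctx, mech, mstate, purview) {
  key <- paste0("E|", paste(mech, mstate, sep = ":", collapse = ","),
                "|", paste(purview, collapse = ","))
  hit <- ctx$cache[[key]]
  if (!is.null(hit)) return(hit)
  on <- vapply(purview, function(z) effect_marginal(ctx, mech, mstate, z),
               numeric(1))
  out <- bernoulli_product(on)
  ctx$cache[[key]] <- out
  out
}

ctx_cause_repertoire <- function(ctx, mech, mstate, purview) {
  key <- paste0("C|", paste(mech, mstate, sep = ":", collapse = ","),
                "|", paste(purview, collapse = ","))
  hit <- ctx$cache[[key]]
  if (!is.null(hit)) return(hit)
  prod_dist <- rep(1, 2L^length(purview))
  for (k in seq_along(mech)) {
    qk <- ctx$q[[mech[k]]][[mstate[k] + 1L]]
    if (is.null(qk)) {
      attr(prod_dist, "undefined") <- TRUE
      ctx$cache[[key]] <- prod_dist
      return(prod_dist)
    }
    prod_dist <- prod_dist * marginal_onto(ctx, qk, purview)
  }
  s <- sum(prod_dist)
  if (s == 0) {
    attr(prod_dist, "undefined") <- TRUE
  } else {
    prod_dist <- prod_dist / s
  }
  ctx$cache[[key]] <- prod_dist
  prod_dist
}

ctx_unconstrained <- function(ctx, direction, purview) {
  if (direction == "cause") {
    rep(1 / 2L^length(purview), 2L^length(purview))
  } else {
    bernoulli_product(ctx$uncon_on[purview])
  }
}

is_undefined <- function(dist) isTRUE(attr(dist, "undefined"))

# ---- public repertoire interface -------------------------------------------

new_repertoire <- function(dist, direction, purview, labels,
                           mechanism, mech_state, undefined = FALSE) {
  structure(
    list(
      dist = as.numeric(dist),
      direction = direction,
      purview = purview,
      purview_labels = labels[purview],
      mechanism = mechanism,
      mechanism_labels = labels[mechanism],
      mech_state = mech_state,
      undefined = undefined
    ),
    class = "repertoire"
  )
}

#' @export
print.repertoire <- function(x, ...) {
  mech <- if (length(x$mechanism) == 0) "(unconstrained)" else
    paste0(paste(x$mechanism_labels, collapse = ""), "=",
           state_label(x$mech_state))
  cat(sprintf(
    "<%s repertoire> mechanism %s over purview {%s}%s\n",
    x$direction, mech, paste(x$purview_labels, collapse = ","),
    if (x$undefined) " [undefined]" else ""
  ))
  d <- x$dist
  names(d) <- subset_state_labels(length(x$purview))
  print(round(d, 4))
  invisible(x)
}

#' Tidy a repertoire into a tibble
#'
#' @param x A `repertoire` object.
#' @param ... Unused.
#' @return A tibble with one row per purview state: `state` (bit string,
#'   positional in purview order) and `probability`.
#' @exportS3Method tibble::as_tibble
as_tibble.repertoire <- function(x, ...) {
  tibble::tibble(
    state = subset_state_labels(length(x$purview)),
    probability = x$dist
  )
}

resolve_mech <- function(x, mechanism, mech_state) {
  mech <- resolve_nodes(mechanism, x$node_labels)
  mech_state <- as.integer(mech_state)
  stopifnot(length(mech_state) == length(mech), all(mech_state %in% c(0L, 1L)))
  o <- order(mech)
  list(nodes = mech[o], state = mech_state[o])
}

#' Cause and effect repertoires of a mechanism over a purview
#'
#' `effect_repertoire()` gives the distribution a mechanism in its current
#' state specifies over the next state of the purview nodes, with all
#' non-mechanism nodes causally marginalized (fed independent maximum-entropy
#' noise) and the purview nodes factorised to discount common-input
#' correlations. `cause_repertoire()` gives the distribution over prior
#' purview states via per-element Bayesian inversion under a uniform
#' perturbation prior, multiplied across mechanism elements and renormalized.
#' `unconstrained_repertoire()` is the comparison distribution specified by
#' the empty mechanism: uniform on the cause side, the product of
#' unconditional node marginals on the effect side.
#'
#' When a mechanism state is unreachable from every prior state the cause
#' repertoire is undefined; the returned object carries `undefined = TRUE`
#' (with a warning) and downstream irreducibility analyses treat it as
#' specifying no information.
#'
#' @param x A `tpm` object (must have a state-by-node form).
#' @param mechanism Mechanism nodes (labels or indices); may be empty
#'   (`integer(0)`) to obtain the unconstrained repertoire.
#' @param mech_state 0/1 values of the mechanism nodes, in the same order.
#' @param purview Non-empty purview nodes (labels or indices).
#' @param direction `"cause"` or `"effect"` (for
#'   `unconstrained_repertoire()`).
#' @return A `repertoire` object; its `dist` is a probability vector over
#'   purview states in little-endian order (first purview node, in node-index
#'   order, varies fastest).
#' @examples
#' mcx <- fixture_tpm("mcx")
#' effect_repertoire(mcx, "C", 1, "M") # p(M_t+1 = 1) = 0.75
#' cause_repertoire(mcx, c("M", "C"), c(0, 1), c("M", "C", "X"))
#' @export
effect_repertoire <- function(x, mechanism, mech_state, purview) {
  ctx <- if (inherits(x, "tpm")) tpm_ctx(x) else x
  m <- resolve_mech_ctx(ctx, mechanism, mech_state)
  Z <- sort(resolve_nodes(purview, ctx$node_labels))
  if (length(Z) == 0) stop("purview must be non-empty")
  dist <- ctx_effect_repertoire(ctx, m$nodes, m$state, Z)
  new_repertoire(dist, "effect", Z, ctx$node_labels, m$nodes, m$state)
}

#' @rdname effect_repertoire
#' @export
cause_repertoire <- function(x, mechanism, mech_state, purview) {
  ctx <- if (inherits(x, "tpm")) tpm_ctx(x) else x
  m <- resolve_mech_ctx(ctx, mechanism, mech_state)
  Z <- sort(resolve_nodes(purview, ctx$node_labels))
  if (length(Z) == 0) stop("purview must be non-empty")
  if (length(m$nodes) == 0) {
    return(new_repertoire(ctx_unconstrained(ctx, "cause", Z), "cause", Z,
                          ctx$node_labels, integer(0), integer(0)))
  }
  dist <- ctx_cause_repertoire(ctx, m$nodes, m$state, Z)
  und <- is_undefined(dist)
  if (und) {
    warning("mechanism state unreachable from every prior state; ",
            "cause repertoire undefined")
    dist <- rep(NA_real_, length(dist))
  }
  new_repertoire(dist, "cause", Z, ctx$node_labels, m$nodes, m$state,
                 undefined = und)
}

resolve_mech_ctx <- function(ctx, mechanism, mech_state) {
  mech <- resolve_nodes(mechanism, ctx$node_labels)
  mech_state <- as.integer(mech_state)
  stopifnot(length(mech_state) == length(mech), all(mech_state %in% c(0L, 1L)))
  o <- order(mech)
  list(nodes = mech[o], state = mech_state[o])
}

#' @rdname effect_repertoire
#' @export
unconstrained_repertoire <- function(x, direction = c("cause", "effect"),
                                     purview) {
  direction <- match.arg(direction)
  ctx <- if (inherits(x, "tpm")) tpm_ctx(x) else x
  Z <- sort(resolve_nodes(purview, ctx$node_labels))
  if (length(Z) == 0) stop("purview must be non-empty")
  new_repertoire(ctx_unconstrained(ctx, direction, Z), direction, Z,
                 ctx$node_labels, integer(0), integer(0))
}

#' Literal-summation repertoire (independent oracle)
#'
#' Computes the same repertoires as [cause_repertoire()] and
#' [effect_repertoire()] by explicit enumeration of every completion of the
#' marginalized variables, taking node conditionals from the joint
#' state-by-state matrix and using no algebraic shortcuts. Intended as an
#' independent cross-check in tests; restricted to small systems.
#'
#' @inheritParams effect_repertoire
#' @return A `repertoire` object.
#' @export
brute_force_repertoire <- function(x, mechanism, mech_state, purview,
                                   direction = c("cause", "effect")) {
  direction <- match.arg(direction)
  stopifnot(inherits(x, "tpm"))
  if (x$n_nodes > 5) stop("brute-force oracle restricted to n <= 5")
  n <- x$n_nodes
  N <- 2L^n
  B <- state_grid(n)
  sbs <- x$state_by_state
  m <- resolve_mech(x, mechanism, mech_state)
  Z <- sort(resolve_nodes(purview, x$node_labels))
  if (length(Z) == 0) stop("purview must be non-empty")
  # node conditional p(node i = b at t | do(prior row r)) from the joint
  p_node <- function(i, b, r) {
    cols <- which(B[, i] == b)
    sum(sbs[r, cols])
  }
  if (direction == "effect") {
    W <- setdiff(seq_len(n), m$nodes) # marginalized variables at t
    BW <- state_grid(max(length(W), 1L))
    per_node_on <- vapply(Z, function(zi) {
      tot <- 0
      nW <- if (length(W)) nrow(BW) else 1L
      for (wrow in seq_len(nW)) {
        full <- integer(n)
        full[m$nodes] <- m$state
        if (length(W)) full[W] <- BW[wrow, seq_along(W)]
        tot <- tot + p_node(zi, 1L, state_index(full))
      }
      tot / nW
    }, numeric(1))
    BZ <- state_grid(length(Z))
    dist <- vapply(seq_len(nrow(BZ)), function(zr) {
      prod(ifelse(BZ[zr, ] == 1L, per_node_on, 1 - per_node_on))
    }, numeric(1))
    return(new_repertoire(dist, "effect", Z, x$node_labels, m$nodes, m$state))
  }
  # cause side
  if (length(m$nodes) == 0) {
    dist <- rep(1 / 2L^length(Z), 2L^length(Z))
    return(new_repertoire(dist, "cause", Z, x$node_labels, integer(0),
                          integer(0)))
  }
  Y <- setdiff(seq_len(n), Z) # marginalized variables at t-1
  BY <- state_grid(max(length(Y), 1L))
  BZ <- state_grid(length(Z))
  elem <- lapply(seq_along(m$nodes), function(k) {
    i <- m$nodes[k]; b <- m$state[k]
    den <- sum(vapply(seq_len(N), function(r) p_node(i, b, r), numeric(1)))
    if (den == 0) return(NULL)
    vapply(seq_len(nrow(BZ)), function(zr) {
      tot <- 0
      nY <- if (length(Y)) nrow(BY) else 1L
      for (yrow in seq_len(nY)) {
        full <- integer(n)
        full[Z] <- BZ[zr, ]
        if (length(Y)) full[Y] <- BY[yrow, seq_along(Y)]
        tot <- tot + p_node(i, b, state_index(full))
      }
      tot / den
    }, numeric(1))
  })
  if (any(vapply(elem, is.null, logical(1)))) {
    warning("mechanism state unreachable; cause repertoire undefined")
    return(new_repertoire(rep(NA_real_, nrow(BZ)), "cause", Z, x$node_labels,
                          m$nodes, m$state, undefined = TRUE))
  }
  dist <- Reduce(`*`, elem)
  s <- sum(dist)
  if (s == 0) {
    warning("zero normalizer; cause repertoire undefined")
    return(new_repertoire(rep(NA_real_, nrow(BZ)), "cause", Z, x$node_labels,
                          m$nodes, m$state, undefined = TRUE))
  }
  new_repertoire(dist / s, "cause", Z, x$node_labels, m$nodes, m$state)
}
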