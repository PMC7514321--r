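# Transition probability matrices of discrete dynamical causal networks, in
# two interconvertible dialects:
#   state-by-state: |Omega| x |Omega| row-stochastic, rows = prior state
#   state-by-node:  |Omega| x n matrix of per-node on-probabilities
# The state-by-node form exists iff node updates are conditionally independent
# given the prior state, p(v_t | v_{t-1}) = prod_i p(v_{i,t} | v_{t-1}).

TOL_STOCHASTIC <- 1e-9
TOL_CLIP <- 1e-12

new_tpm <- function(n, node_labels, sbs, sbn, independent) {
  structure(
    list(
      n_nodes = n,
      node_labels = node_labels,
      state_by_state = sbs,
      state_by_node = sbn,
      independent = independent,
      state_ordering = "little_endian"
    ),
    class = "tpm"
  )
}

default_labels <- function(n) {
  if (n <= 26) LETTERS[seq_len(n)] else paste0("N", seq_len(n))
}

clip01 <- function(p) {
  bad <- p < -TOL_CLIP | p > 1 + TOL_CLIP
  if (any(bad)) stop("probabilities outside [0, 1]")
  pmin(pmax(p, 0), 1)
}

# expand per-node on-probabilities (N x n) into the joint state-by-state
# matrix under conditional independence
sbn_to_sbs <- function(sbn) {
  out <- matrix(1, nrow(sbn), 1)
  for (i in seq_len(ncol(sbn))) {
    p <- sbn[, i]
    out <- cbind(out * (1 - p), out * p)
  }
  out
}

# node-i on-probability implied by a state-by-state matrix (exact marginal)
sbs_node_marginals <- function(sbs, n) {
  B <- state_grid(n)
  vapply(seq_len(n), function(i) as.numeric(sbs %*% B[, i]), numeric(nrow(sbs)))
}

#' Build a transition probability matrix from node mechanisms
#'
#' Assembles the system TPM of a dynamical causal network from one mechanism
#' per node. A mechanism is the node's conditional on-probability
#' `p(v_i = 1 at t | full system state at t-1)`, given either as a numeric
#' vector over all `2^n` prior states (little-endian order, see
#' [state_grid()]) or as a function of the prior state vector. The joint
#' matrix is the product of the per-node conditionals, which encodes the
#' assumption of no instantaneous causation between nodes.
#'
#' @param mechanisms A list with one element per node: numeric vectors of
#'   length `2^n` with values in `[0, 1]`, or functions mapping a 0/1 prior
#'   state vector to the node's on-probability. Names, if present, become the
#'   node labels.
#' @param node_labels Optional character vector of node names.
#' @return A `tpm` object carrying both dialects.
#' @examples
#' # two-node system: A copies B, B negates A
#' tp <- build_tpm(list(
#'   A = function(s) s[2],
#'   B = function(s) 1 - s[1]
#' ))
#' state_by_state(tp)
#' @seealso [tpm_from_matrix()], [fixture_tpm()]
#' @export
build_tpm <- function(mechanisms, node_labels = NULL) {
  stopifnot(is.list(mechanisms), length(mechanisms) >= 1)
  n <- length(mechanisms)
  N <- 2L^n
  B <- state_grid(n)
  cols <- lapply(mechanisms, function(m) {
    if (is.function(m)) {
      m <- vapply(seq_len(N), function(r) as.numeric(m(B[r, ])), numeric(1))
    }
    m <- as.numeric(m)
    if (length(m) != N) {
      stop("each mechanism must be defined over all 2^n = ", N, " prior states")
    }
    clip01(m)
  })
  sbn <- do.call(cbind, cols)
  if (is.null(node_labels)) node_labels <- names(mechanisms)
  if (is.null(node_labels)) node_labels <- default_labels(n)
  stopifnot(length(node_labels) == n)
  dimnames(sbn) <- list(apply(B, 1, state_label), node_labels)
  sbs <- sbn_to_sbs(sbn)
  dimnames(sbs) <- list(rownames(sbn), rownames(sbn))
  new_tpm(n, node_labels, sbs, sbn, independent = TRUE)
}

#' Create a TPM from an explicit matrix
#'
#' Wraps a matrix in either dialect as a `tpm` object. State-by-state input is
#' validated for row-stochasticity and factorised into state-by-node form when
#' the node updates are conditionally independent; with `strict = TRUE`
#' (default) a matrix that cannot be factorised is rejected, since all
#' mechanism-level analyses require the factorised form. With
#' `strict = FALSE` such a matrix is kept with `state_by_node = NULL` for
#' state-by-state-only workflows (entropy rates, effective information).
#'
#' @param mat Numeric matrix: `2^n x 2^n` (state-by-state) or `2^n x n`
#'   (state-by-node), little-endian state order.
#' @param dialect `"state_by_state"` or `"state_by_node"`.
#' @param node_labels Optional node names.
#' @param strict Reject state-by-state matrices violating conditional
#'   independence (reconstruction error above `tol`)?
#' @param tol Numerical tolerance for stochasticity and factorisation checks.
#' @return A `tpm` object.
#' @examples
#' tpm_from_matrix(matrix(c(0, 0, 1, 1), 2, 2), "state_by_state")
#' @export
tpm_from_matrix <- function(mat,
                            dialect = c("state_by_state", "state_by_node"),
                            node_labels = NULL,
                            strict = TRUE,
                            tol = TOL_STOCHASTIC) {
  dialect <- match.arg(dialect)
  mat <- as.matrix(mat)
  storage.mode(mat) <- "double"
  if (dialect == "state_by_node") {
    n <- ncol(mat)
    if (nrow(mat) != 2^n) stop("state-by-node matrix must be 2^n x n")
    mechs <- lapply(seq_len(n), function(i) mat[, i])
    if (!is.null(node_labels)) names(mechs) <- node_labels else
      names(mechs) <- colnames(mat) %||% default_labels(n)
    return(build_tpm(mechs))
  }
  N <- nrow(mat)
  n <- as.integer(round(log2(N)))
  if (2^n != N || ncol(mat) != N) stop("state-by-state matrix must be 2^n x 2^n")
  mat <- clip01(mat)
  rs <- rowSums(mat)
  if (any(abs(rs - 1) > tol)) stop("state-by-state rows must sum to 1")
  if (is.null(node_labels)) node_labels <- default_labels(n)
  stopifnot(length(node_labels) == n)
  labs <- apply(state_grid(n), 1, state_label)
  dimnames(mat) <- list(labs, labs)
  sbn <- sbs_node_marginals(mat, n)
  recon <- sbn_to_sbs(sbn)
  independent <- max(abs(recon - mat)) <= max(tol, 1e-9)
  if (!independent) {
    if (strict) {
      stop(
        "matrix does not factorise over nodes (conditional independence ",
        "violated); pass strict = FALSE to keep a state-by-state-only TPM"
      )
    }
    sbn <- NULL
  } else {
    dimnames(sbn) <- list(labs, node_labels)
  }
  new_tpm(n, node_labels, mat, sbn, independent)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Access TPM dialects and basic predicates
#'
#' `state_by_state()` and `state_by_node()` return the two matrix dialects;
#' `sbs_to_sbn()` extracts (or recomputes) the per-node on-probability table
#' from any TPM, erroring in strict mode when the joint matrix does not
#' factorise; `is_deterministic()` tests whether every row is one-hot.
#'
#' @param x A `tpm` object.
#' @param strict Error if the factorised form does not reproduce the joint
#'   matrix?
#' @return Matrices, or a logical for `is_deterministic()`.
#' @export
state_by_state <- function(x) {
  stopifnot(inherits(x, "tpm"))
  x$state_by_state
}

#' @rdname state_by_state
#' @export
state_by_node <- function(x) {
  stopifnot(inherits(x, "tpm"))
  x$state_by_node
}

#' @rdname state_by_state
#' @export
sbs_to_sbn <- function(x, strict = TRUE) {
  stopifnot(inherits(x, "tpm"))
  if (!is.null(x$state_by_node)) return(x$state_by_node)
  if (strict) {
    stop("TPM violates conditional independence; no state-by-node form exists")
  }
  m <- sbs_node_marginals(x$state_by_state, x$n_nodes)
  dimnames(m) <- list(rownames(x$state_by_state), x$node_labels)
  m
}

#' @rdname state_by_state
#' @export
is_deterministic <- function(x) {
  stopifnot(inherits(x, "tpm"))
  all(x$state_by_state %in% c(0, 1))
}

#' @export
print.tpm <- function(x, ...) {
  kind <- if (is_deterministic(x)) "deterministic" else "probabilistic"
  cat(sprintf(
    "<tpm> %d binary nodes (%s), %s, little-endian state order\n",
    x$n_nodes, paste(x$node_labels, collapse = ","), kind
  ))
  if (!is.null(x$state_by_node)) {
    cat("state-by-node on-probabilities:\n")
    print(round(x$state_by_node, 4))
  } else {
    cat("state-by-state only (node updates not conditionally independent)\n")
    print(round(x$state_by_state, 4))
  }
  invisible(x)
}

#' Tidy a TPM into a long transition table
#'
#' @param x A `tpm` object.
#' @param ... Unused.
#' @return A tibble with columns `prior`, `state`, `probability`, one row per
#'   (prior state, next state) pair with non-zero or zero probability.
#' @exportS3Method tibble::as_tibble
as_tibble.tpm <- function(x, ...) {
  labs <- rownames(x$state_by_state)
  tibble::tibble(
    prior = rep(labs, times = length(labs)),
    state = rep(labs, each = length(labs)),
    probability = as.vector(t(x$state_by_state))
  )
}

#' Connectivity implied by a TPM
#'
#' Derives the causal adjacency matrix of the network: entry `(i, j)` is 1
#' iff node `j`'s on-probability differs between at least one pair of prior
#' states that differ only in node `i` — i.e. node `j`'s mechanism actually
#' depends on node `i`.
#'
#' @param x A `tpm` object.
#' @return An `n x n` 0/1 matrix (rows = source, columns = target) with node
#'   labels as dimnames.
#' @examples
#' connectivity(fixture_tpm("mcx"))
#' @export
connectivity <- function(x) {
  stopifnot(inherits(x, "tpm"))
  n <- x$n_nodes
  sbn <- x$state_by_node %||% sbs_node_marginals(x$state_by_state, n)
  adj <- matrix(0L, n, n, dimnames = list(x$node_labels, x$node_labels))
  for (i in seq_len(n)) {
    lo <- which(state_grid(n)[, i] == 0L)
    hi <- lo + 2L^(i - 1L)
    for (j in seq_len(n)) {
      if (any(abs(sbn[lo, j] - sbn[hi, j]) > TOL_STOCHASTIC)) adj[i, j] <- 1L
    }
  }
  adj
}

#' Condition a TPM on a partial prior state and marginalize the output
#'
#' Computes the distribution of a subset of nodes at `t` given fixed values
#' for a subset of nodes at `t-1`, averaging uniformly over all states of the
#' unfixed prior nodes (causal marginalization). This is the plain conditional
#' distribution derived from the joint matrix — unlike an effect repertoire it
#' does not factorise the output nodes.
#'
#' @param x A `tpm` object.
#' @param fixed Named vector/list of 0/1 values for the fixed prior nodes
#'   (names = node labels), or an unnamed full state.
#' @param out_nodes Nodes at `t` to retain (labels or indices).
#' @return A named numeric probability vector over the states of `out_nodes`
#'   (little-endian order within the subset).
#' @examples
#' mcx <- fixture_tpm("mcx")
#' condition_and_marginalize(mcx, c(C = 1), "M") # p(M_t+1) = (0.25, 0.75)
#' @export
condition_and_marginalize <- function(x, fixed, out_nodes) {
  stopifnot(inherits(x, "tpm"))
  n <- x$n_nodes
  out <- resolve_nodes(out_nodes, x$node_labels)
  if (length(out) == 0) stop("out_nodes must be non-empty")
  if (is.null(names(fixed)) && length(fixed) == n) {
    fix_idx <- seq_len(n)
    fix_val <- as.integer(unlist(fixed))
  } else {
    if (is.null(names(fixed))) stop("fixed must be named or a full state")
    fix_idx <- resolve_nodes(names(fixed), x$node_labels)
    fix_val <- as.integer(unlist(fixed))
  }
  stopifnot(all(fix_val %in% c(0L, 1L)))
  B <- state_grid(n)
  rows <- rep(TRUE, nrow(B))
  for (k in seq_along(fix_idx)) rows <- rows & (B[, fix_idx[k]] == fix_val[k])
  avg <- colMeans(x$state_by_state[rows, , drop = FALSE])
  sub_idx <- state_index(B[, out, drop = FALSE])
  dist <- as.numeric(rowsum(avg, sub_idx))
  names(dist) <- subset_state_labels(length(out))
  dist / sum(dist)
}
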