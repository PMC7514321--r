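# State-space conventions: binary nodes, little-endian enumeration.
# Row/state index r (1-based) encodes the state whose bit for node i is
# (r - 1) >> (i - 1) & 1, i.e. node 1 varies fastest. Printed bit strings
# such as "011" map positionally: first character = node 1.

#' Enumerate all binary states of a set of nodes
#'
#' Returns the full state space of `n` binary nodes as a matrix with one row
#' per state in little-endian order (node 1 varies fastest), matching the row
#' and column ordering of all transition probability matrices in the package.
#'
#' @param n Number of binary nodes.
#' @return An integer matrix with `2^n` rows and `n` columns of 0/1 entries.
#' @examples
#' state_grid(2)
#' @export
state_grid <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  n <- as.integer(n)
  N <- 2L^n
  m <- matrix(0L, N, n)
  for (i in seq_len(n)) {
    m[, i] <- bitwAnd(bitwShiftR(0:(N - 1L), i - 1L), 1L)
  }
  m
}

#' Convert between binary state tuples and state indices
#'
#' `state_index()` maps a 0/1 state vector (or matrix of states, one per row)
#' to its 1-based little-endian index; `index_state()` is the inverse.
#'
#' @param bits Integer vector of 0/1 values (one per node), or a matrix with
#'   one state per row.
#' @param r 1-based state index (vectorised).
#' @param n Number of nodes.
#' @return `state_index()`: integer index/indices; `index_state()`: a 0/1
#'   matrix with one state per row.
#' @examples
#' state_index(c(0, 1, 1)) # 7
#' index_state(7, 3)
#' @export
state_index <- function(bits) {
  if (is.matrix(bits)) {
    as.integer(1 + bits %*% 2^(seq_len(ncol(bits)) - 1))
  } else {
    as.integer(1 + sum(bits * 2^(seq_along(bits) - 1)))
  }
}

#' @rdname state_index
#' @export
index_state <- function(r, n) {
  out <- matrix(0L, length(r), n)
  for (i in seq_len(n)) {
    out[, i] <- bitwAnd(bitwShiftR(as.integer(r) - 1L, i - 1L), 1L)
  }
  out
}

# "011" -> c(0L, 1L, 1L); positional, first character = node 1
parse_state <- function(s) {
  if (is.numeric(s)) {
    stopifnot(all(s %in% c(0, 1)))
    return(as.integer(s))
  }
  stopifnot(is.character(s), length(s) == 1)
  bits <- as.integer(strsplit(s, "")[[1]])
  stopifnot(all(bits %in% c(0L, 1L)))
  bits
}

state_label <- function(bits) paste0(bits, collapse = "")

# labels for all states over a node subset, little-endian
subset_state_labels <- function(k) {
  apply(state_grid(max(k, 1L)), 1, state_label)
}

# Resolve node identifiers (integer indices or label strings) to indices.
resolve_nodes <- function(nodes, labels) {
  if (is.null(nodes)) return(integer(0))
  if (is.character(nodes)) {
    idx <- match(nodes, labels)
    if (anyNA(idx)) {
      stop("unknown node label(s): ", paste(nodes[is.na(idx)], collapse = ", "))
    }
    return(as.integer(idx))
  }
  nodes <- as.integer(nodes)
  if (length(nodes) && (min(nodes) < 1 || max(nodes) > length(labels))) {
    stop("node index out of range")
  }
  nodes
}
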