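# Fixture builders and independent oracles used across the test files.
# Everything here is generated in code; no stored data.

mcx <- fixture_tpm("mcx")

# all 256 deterministic 2-node systems (every successor map)
all_deterministic_2node <- function() {
  maps <- expand.grid(s1 = 1:4, s2 = 1:4, s3 = 1:4, s4 = 1:4)
  lapply(seq_len(nrow(maps)), function(r) {
    targets <- as.integer(maps[r, ])
    sbn <- state_grid(2)[targets, , drop = FALSE]
    storage.mode(sbn) <- "double"
    build_tpm(list(A = sbn[, 1], B = sbn[, 2]))
  })
}

# a 2-node system with perfectly correlated outputs: p((0,0)|.) = p((1,1)|.)
# = 1/2; violates conditional independence, state-by-state only
correlated_2node_sbs <- function() {
  matrix(rep(c(0.5, 0, 0, 0.5), each = 4), 4, 4)
}

# feedforward 3-node system: A -> B -> C chain, no feedback anywhere
feedforward_chain <- function() {
  build_tpm(list(
    A = function(s) 1 - s[1],      # A depends only on itself
    B = function(s) s[1],          # B copies A
    C = function(s) s[2]           # C copies B
  ))
}

# two disconnected sub-networks: {A,B} flip-flop and {C} self-NOT
disconnected_pair <- function() {
  build_tpm(list(
    A = function(s) s[2],
    B = function(s) s[1],
    C = function(s) 1 - s[3]
  ))
}

# independent oracle for phi: enumerate partitions with a different strategy
# (expand.grid over part labellings, deduplicated) and compute repertoires by
# literal summation (brute_force_repertoire); minimise the divergence.
oracle_phi <- function(x, mech_nodes, mech_state, direction) {
  n <- x$n_nodes
  purview <- seq_len(n)
  intact <- brute_force_repertoire(x, mech_nodes, mech_state, purview,
                                   direction)
  if (intact$undefined) return(0)
  uncon_dist <- function(Z) {
    r <- brute_force_repertoire(x, integer(0), integer(0), Z, direction)
    r$dist
  }
  if (length(mech_nodes) == 1) {
    return(kld_bits(intact$dist, uncon_dist(purview)))
  }
  k <- length(mech_nodes)
  # mechanism part labellings via expand.grid, canonicalised to dedupe
  labelings <- expand.grid(rep(list(seq_len(k)), k))
  seen <- character(0)
  best <- Inf
  for (li in seq_len(nrow(labelings))) {
    lab <- as.integer(labelings[li, ])
    # canonical form: relabel in order of first appearance
    canon <- match(lab, unique(lab))
    key <- paste(canon, collapse = "")
    if (key %in% seen) next
    seen <- c(seen, key)
    m <- max(canon)
    if (m < 2) next
    blocks <- split(seq_len(k), canon)
    # purview assignments: each purview node to a block or 0 (leftover)
    assigns <- expand.grid(rep(list(0:m), n))
    for (ai in seq_len(nrow(assigns))) {
      a <- as.integer(assigns[ai, ])
      dist <- rep(1, 2^n)
      ok <- TRUE
      for (b in seq_len(m)) {
        Zb <- purview[a == b]
        if (length(Zb) == 0) next
        part <- brute_force_repertoire(
          x, mech_nodes[blocks[[b]]], mech_state[blocks[[b]]], Zb, direction
        )
        if (part$undefined) { ok <- FALSE; break }
        dist <- dist * expand_subdist(part$dist, Zb, purview)
      }
      if (!ok) next
      left <- purview[a == 0]
      if (length(left)) {
        dist <- dist * expand_subdist(uncon_dist(left), left, purview)
      }
      val <- suppressWarnings(kld_bits(intact$dist, dist))
      if (val < best) best <- val
    }
  }
  if (best < 1e-9) 0 else best
}

# expand a distribution over node subset Z to a factor over purview P
expand_subdist <- function(dist, Z, P) {
  BP <- state_grid(length(P))
  idx <- 1 + as.integer(BP[, match(Z, P), drop = FALSE] %*%
                          2^(seq_along(Z) - 1))
  dist[idx]
}

# enumerate all non-empty subsets of 1..n as index vectors
all_subsets <- function(n) {
  lapply(seq_len(2^n - 1), function(mask) which(bitwAnd(
    bitwShiftR(mask, 0:(n - 1)), 1L) == 1L))
}
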