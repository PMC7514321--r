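# Samplers, exhaustive enumeration of reversible systems, time reversal,
# attractor analysis, and metric sweeps.

#' Sample random binary systems
#'
#' `sample_deterministic_tpm()` draws each prior state's successor uniformly
#' at random from the state space (one-hot rows);
#' `sample_probabilistic_tpm()` fills every entry of the state-by-node table
#' with an independent Uniform(0, 1) on-probability, so conditional
#' independence holds by construction.
#'
#' @param n Number of binary nodes.
#' @param seed Optional integer seed; when given, the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @param node_labels Optional node names.
#' @return A `tpm` object.
#' @examples
#' sample_deterministic_tpm(3, seed = 1)
#' @export
sample_deterministic_tpm <- function(n, seed = NULL, node_labels = NULL) {
  draw <- function() sample.int(2L^n, 2L^n, replace = TRUE)
  targets <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  tpm_from_targets(targets, n, node_labels)
}

#' @rdname sample_deterministic_tpm
#' @export
sample_probabilistic_tpm <- function(n, seed = NULL, node_labels = NULL) {
  N <- 2L^n
  draw <- function() matrix(stats::runif(N * n), N, n)
  sbn <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  tpm_from_matrix(sbn, "state_by_node", node_labels = node_labels)
}

# deterministic tpm from a successor map (targets[r] = next-state index)
tpm_from_targets <- function(targets, n, node_labels = NULL) {
  B <- state_grid(n)
  sbn <- B[targets, , drop = FALSE]
  storage.mode(sbn) <- "double"
  mechs <- lapply(seq_len(n), function(i) sbn[, i])
  names(mechs) <- node_labels %||% default_labels(n)
  build_tpm(mechs)
}

#' Reversibility and ergodicity of a system
#'
#' A system is reversible when it is deterministic and its state-by-state
#' matrix is a permutation matrix (every state has exactly one predecessor
#' and one successor); such systems attain the maximal effective information
#' of `n` bits. A reversible system is ergodic-reversible (ER) when the
#' permutation is a single cycle through all `2^n` states, so the observed
#' stationary distribution is uniform.
#'
#' @param x A `tpm` object.
#' @return Logical. `is_ergodic_reversible()` errors on non-reversible input.
#' @examples
#' is_reversible(fixture_tpm("mcx")) # FALSE: two states map to 000
#' is_ergodic_reversible(fixture_tpm("shift3")) # TRUE
#' @export
is_reversible <- function(x) {
  stopifnot(inherits(x, "tpm"))
  is_deterministic(x) && all(colSums(x$state_by_state) == 1)
}

#' @rdname is_reversible
#' @export
is_ergodic_reversible <- function(x) {
  if (!is_reversible(x)) stop("system is not reversible")
  perm <- successor_map(x)
  # single cycle of length 2^n
  cur <- 1L
  for (step in seq_along(perm)) {
    cur <- perm[cur]
    if (cur == 1L) return(step == length(perm))
  }
  FALSE
}

# successor state index for each prior state of a deterministic tpm
successor_map <- function(x) {
  stopifnot(is_deterministic(x))
  max.col(x$state_by_state, ties.method = "first")
}

#' Enumerate all reversible binary systems
#'
#' Generates one system per permutation of the `2^n` states, in lexicographic
#' permutation order; there are `(2^n)!` of them, of which `(2^n - 1)!` are
#' ergodic. Exhaustive enumeration is guarded to `n <= 3` (40,320 systems);
#' beyond that the count is astronomically large.
#'
#' @param n Number of nodes (`n <= 3`).
#' @param as `"permutation"` (default) for an integer matrix with one
#'   successor map per row — convert rows with [tpm_from_permutation()] — or
#'   `"tpm"` for a list of `tpm` objects.
#' @return See `as`.
#' @examples
#' nrow(enumerate_reversible(2)) # 24
#' @export
enumerate_reversible <- function(n, as = c("permutation", "tpm")) {
  as <- match.arg(as)
  stopifnot(n >= 1)
  if (n > 3) stop("exhaustive enumeration is limited to n <= 3: (2^n)! grows too fast")
  perms <- all_permutations(2L^n)
  if (as == "permutation") return(perms)
  lapply(seq_len(nrow(perms)), function(r) tpm_from_permutation(perms[r, ]))
}

#' @rdname enumerate_reversible
#' @param perm Integer vector: `perm[r]` is the successor state index of
#'   prior state `r`.
#' @param node_labels Optional node names.
#' @export
tpm_from_permutation <- function(perm, node_labels = NULL) {
  N <- length(perm)
  n <- as.integer(round(log2(N)))
  stopifnot(2^n == N, sort(perm) == seq_len(N))
  tpm_from_targets(as.integer(perm), n, node_labels)
}

# all permutations of 1..N in lexicographic order (N! x N matrix)
all_permutations <- function(N) {
  if (N == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(N - 1L)
  block <- nrow(sub)
  out <- matrix(0L, block * N, N)
  for (k in seq_len(N)) {
    rows <- ((k - 1L) * block + 1L):(k * block)
    rest <- seq_len(N)[-k]
    out[rows, 1] <- k
    out[rows, -1] <- matrix(rest[sub], block, N - 1L)
  }
  out
}

#' Time-reverse a reversible system
#'
#' The dynamical equivalent running the same state cycle backwards: the
#' inverse permutation (transpose of the permutation matrix). An involution
#' that preserves reversibility and ergodicity — but generally not the
#' system's mechanisms, connectivity, or composition.
#'
#' @param x A reversible `tpm`.
#' @return A `tpm` object.
#' @examples
#' tr <- time_reverse(fixture_tpm("shift3"))
#' is_ergodic_reversible(tr)
#' @export
time_reverse <- function(x) {
  if (!is_reversible(x)) stop("time reversal is defined for reversible systems only")
  perm <- successor_map(x)
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  tpm_from_targets(inv, x$n_nodes, x$node_labels)
}

#' Attractor structure of a deterministic system
#'
#' Decomposes the functional digraph of a deterministic TPM into its
#' attractors (fixed points and periodic cycles) and their basins. For a
#' reversible system every state lies on a cycle; for an ER system there is a
#' single cycle of length `2^n`.
#'
#' @param x A deterministic `tpm`.
#' @return An `attractor_profile` object: tibble `attractors` (one row per
#'   attractor: `attractor`, `length`, `states` list-column of bit strings,
#'   `basin_size` counting all states draining to it, cycle states included),
#'   plus `n_attractors` and `fixed_points`.
#' @examples
#' attractor_profile(fixture_tpm("mcx"))
#' @export
attractor_profile <- function(x) {
  stopifnot(inherits(x, "tpm"))
  if (!is_deterministic(x)) stop("attractor analysis requires a deterministic TPM")
  perm <- successor_map(x)
  N <- length(perm)
  attractor_of <- integer(N) # 0 = unknown
  cycles <- list()
  for (s in seq_len(N)) {
    if (attractor_of[s] != 0L) next
    path <- integer(0)
    on_path <- integer(N) # position of state in current path, 0 otherwise
    cur <- s
    while (attractor_of[cur] == 0L && on_path[cur] == 0L) {
      path <- c(path, cur)
      on_path[cur] <- length(path)
      cur <- perm[cur]
    }
    if (attractor_of[cur] != 0L) {
      aid <- attractor_of[cur]
    } else {
      cyc <- path[on_path[cur]:length(path)]
      cycles[[length(cycles) + 1L]] <- cyc
      aid <- length(cycles)
    }
    attractor_of[path] <- aid
  }
  labs <- rownames(x$state_by_state)
  tab <- tibble::tibble(
    attractor = seq_along(cycles),
    length = lengths(cycles),
    states = lapply(cycles, function(cyc) labs[cyc]),
    basin_size = vapply(seq_along(cycles),
                        function(a) sum(attractor_of == a), integer(1))
  )
  structure(
    list(
      attractors = tab,
      n_attractors = length(cycles),
      fixed_points = sum(tab$length == 1L),
      attractor_of = attractor_of
    ),
    class = "attractor_profile"
  )
}

#' @export
print.attractor_profile <- function(x, ...) {
  cat(sprintf("<attractor profile> %d attractor(s), %d fixed point(s)\n",
              x$n_attractors, x$fixed_points))
  print(x$attractors)
  invisible(x)
}

#' Sweep metrics across a collection of systems
#'
#' Computes the selected information and integration metrics for each system
#' and returns a tidy table, one row per system — the workhorse for
#' population comparisons such as deterministic vs probabilistic samples or
#' the full reversible family.
#'
#' @param systems A list of `tpm` objects, or a permutation matrix as
#'   returned by [enumerate_reversible()].
#' @param metrics Character subset of `"ei"` (effective information),
#'   `"predictive_information"` (uniform prior), `"sum_phi"` (state-averaged
#'   `sum(phiC)`, `sum(phiE)` and total), `"big_phi"` (state-averaged big
#'   phi), `"reversal_delta"` (difference in total phi and big phi to the
#'   time-reversed system; reversible systems only).
#' @param states `"all"` to average state-dependent metrics over all `2^n`
#'   states, or a single state (bit string / 0/1 vector) to evaluate there.
#' @param out Optional CSV path; the table is also written there.
#' @param progress Print a progress message every `progress` systems
#'   (`0` = silent).
#' @return A tibble with columns `system`, `deterministic`, `reversible`,
#'   `ergodic`, and one column per requested metric.
#' @examples
#' sweep_systems(list(fixture_tpm("mcx"), fixture_tpm("shift3")),
#'               metrics = "ei")
#' @export
sweep_systems <- function(systems,
                          metrics = c("ei", "sum_phi", "big_phi"),
                          states = "all",
                          out = NULL,
                          progress = 0) {
  metrics <- match.arg(metrics,
    c("ei", "predictive_information", "sum_phi", "big_phi", "reversal_delta"),
    several.ok = TRUE)
  if (is.matrix(systems)) {
    systems <- lapply(seq_len(nrow(systems)),
                      function(r) tpm_from_permutation(systems[r, ]))
  }
  rows <- lapply(seq_along(systems), function(k) {
    x <- systems[[k]]
    det <- is_deterministic(x)
    rev <- is_reversible(x)
    row <- tibble::tibble(
      system = k,
      deterministic = det,
      reversible = rev,
      ergodic = rev && is_ergodic_reversible(x)
    )
    if ("ei" %in% metrics) row$ei <- effective_information(x)
    if ("predictive_information" %in% metrics) {
      row$predictive_information <- predictive_information(x)
    }
    needs_state <- any(c("sum_phi", "big_phi", "reversal_delta") %in% metrics)
    if (needs_state) {
      summ <- sweep_state_metrics(x, metrics, states)
      row <- dplyr::bind_cols(row, summ)
    }
    if ("reversal_delta" %in% metrics) {
      if (!rev) {
        row$delta_total_phi <- NA_real_
        row$delta_big_phi <- NA_real_
      } else {
        rsum <- sweep_state_metrics(time_reverse(x), metrics, states)
        row$delta_total_phi <-
          if ("sum_phi" %in% metrics) row$total_phi - rsum$total_phi else NA_real_
        row$delta_big_phi <-
          if ("big_phi" %in% metrics) row$big_phi - rsum$big_phi else NA_real_
      }
    }
    if (progress > 0 && k %% progress == 0) {
      message(sprintf("sweep: %d / %d systems", k, length(systems)))
    }
    row
  })
  tab <- dplyr::bind_rows(rows)
  if (!is.null(out)) utils::write.csv(tab[, !vapply(tab, is.list, logical(1))],
                                      out, row.names = FALSE)
  tab
}

# state-dependent metrics, averaged over all states or at one state
sweep_state_metrics <- function(x, metrics, states) {
  state_list <- if (identical(states, "all")) {
    B <- state_grid(x$n_nodes)
    lapply(seq_len(nrow(B)), function(r) B[r, ])
  } else {
    list(parse_state(states))
  }
  sums_c <- sums_e <- bps <- numeric(length(state_list))
  for (i in seq_along(state_list)) {
    comp <- composition(x, state_list[[i]])
    sums_c[i] <- comp$sum_phi_c
    sums_e[i] <- comp$sum_phi_e
    if ("big_phi" %in% metrics) {
      bps[i] <- big_phi(x, state_list[[i]], comp = comp)$big_phi
    }
  }
  out <- tibble::tibble(.rows = 1)
  if ("sum_phi" %in% metrics) {
    out$sum_phi_c <- mean(sums_c)
    out$sum_phi_e <- mean(sums_e)
    out$total_phi <- mean(sums_c + sums_e)
  }
  if ("big_phi" %in% metrics) out$big_phi <- mean(bps)
  out
}
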