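test_that("partition enumeration has the right size and structure", {
  # 2-part mechanism split x 3 choices per purview node
  ps <- enumerate_partitions(c(1, 2), c(1, 2, 3))
  expect_length(ps, 27)
  # minimal purview: the single node goes to part 1, part 2, or leftover
  ps2 <- enumerate_partitions(c(1, 2), 3)
  expect_length(ps2, 3)
  where <- vapply(ps2, function(p) {
    if (length(p$leftover)) "leftover"
    else if (length(p$parts[[1]]$purview)) "part1" else "part2"
  }, character(1))
  expect_setequal(where, c("part1", "part2", "leftover"))
  # three-element mechanism: 3 bipartitions + 1 tripartition of the mechanism
  ps3 <- enumerate_partitions(1:3, integer(0))
  expect_length(ps3, 4)
  sizes <- vapply(ps3, function(p) length(p$parts), integer(1))
  expect_equal(sort(sizes), c(2, 2, 2, 3))
  # every partition: mechanism parts non-empty, disjoint, exhaustive
  for (p in enumerate_partitions(c(1, 3), c(1, 2))) {
    mechs <- lapply(p$parts, `[[`, "mech")
    expect_true(all(lengths(mechs) > 0))
    expect_equal(sort(unlist(mechs)), c(1, 3))
    pur <- c(unlist(lapply(p$parts, `[[`, "purview")), p$leftover)
    expect_equal(sort(pur), c(1, 2))
  }
  expect_error(enumerate_partitions(2, c(1, 2)), "singleton")
})

test_that("partitioned repertoires cut joint constraints as specified", {
  # cause side, MX=(0,1), split (X_{t-1}|M) x (MC_{t-1}|X): the divergence
  # from the intact repertoire is the minimum information partition value
  psi <- list(
    parts = list(
      list(mech = 1L, purview = 3L),        # M constrains X_{t-1}
      list(mech = 3L, purview = c(1L, 2L))  # X constrains MC_{t-1}
    ),
    leftover = integer(0)
  )
  intact <- cause_repertoire(mcx, c("M", "X"), c(0, 1), 1:3)
  part <- partitioned_repertoire(mcx, c("M", "X"), c(0, 1), 1:3, psi, "cause")
  expect_equal(kld_bits(intact$dist, part$dist), log2(4 / 3),
               tolerance = 1e-9)
  # a vacuous cut: hand the whole purview to MC and nothing to X, on the
  # full mechanism whose X element adds no cause constraint of its own
  psi2 <- list(
    parts = list(
      list(mech = c(1L, 2L), purview = 1:3),
      list(mech = 3L, purview = integer(0))
    ),
    leftover = integer(0)
  )
  part2 <- partitioned_repertoire(mcx, c("M", "C", "X"), c(0, 1, 1), 1:3,
                                  psi2, "cause")
  full <- cause_repertoire(mcx, c("M", "C", "X"), c(0, 1, 1), 1:3)
  expect_equal(part2$dist, full$dist, tolerance = 1e-9)
  # effect side, MCX=(0,1,1), split (CX_{t+1}|MC) x (M_{t+1}|X): replaces the
  # deterministic M_{t+1} value with 0.75 and costs 0.415 bits
  psi3 <- list(
    parts = list(
      list(mech = c(1L, 2L), purview = c(2L, 3L)),
      list(mech = 3L, purview = 1L)
    ),
    leftover = integer(0)
  )
  part3 <- partitioned_repertoire(mcx, c("M", "C", "X"), c(0, 1, 1), 1:3,
                                  psi3, "effect")
  margM <- sum(part3$dist[state_grid(3)[, 1] == 1])
  expect_equal(margM, 0.75)
  intact3 <- effect_repertoire(mcx, c("M", "C", "X"), c(0, 1, 1), 1:3)
  expect_equal(kld_bits(intact3$dist, part3$dist), log2(4 / 3),
               tolerance = 1e-9)
})

test_that("phi reproduces the full per-subset table of the example system", {
  state <- c(0, 1, 1)
  phi_c <- c(M = 1, C = 1, X = 1, MC = 1, MX = log2(4 / 3), CX = 1, MCX = 0)
  phi_e <- c(M = 1 + (1 - entropy_bits(c(0.25, 0.75))),
             C = 1 - entropy_bits(c(0.25, 0.75)),
             X = 1 - entropy_bits(c(0.25, 0.75)),
             MC = 1, MX = 0, CX = log2(4 / 3), MCX = log2(4 / 3))
  subsets <- list(M = 1, C = 2, X = 3, MC = c(1, 2), MX = c(1, 3),
                  CX = c(2, 3), MCX = 1:3)
  for (nm in names(subsets)) {
    s <- subsets[[nm]]
    expect_equal(mechanism_phi(mcx, s, state[s], "cause")$phi,
                 unname(phi_c[nm]), tolerance = 1e-6, label = paste("phiC", nm))
    expect_equal(mechanism_phi(mcx, s, state[s], "effect")$phi,
                 unname(phi_e[nm]), tolerance = 1e-6, label = paste("phiE", nm))
  }
})

test_that("single-node phi equals the closed-form divergence to the unconstrained repertoire", {
  for (k in 1:8) {
    x <- sample_probabilistic_tpm(3, seed = 900 + k)
    st <- index_state(k, 3)[1, ]
    for (i in 1:3) {
      for (dir in c("cause", "effect")) {
        r <- mechanism_phi(x, i, st[i], dir)
        intact <- if (dir == "effect") {
          effect_repertoire(x, i, st[i], 1:3)
        } else {
          cause_repertoire(x, i, st[i], 1:3)
        }
        uncon <- unconstrained_repertoire(x, dir, 1:3)
        expect_equal(r$phi, kld_bits(intact$dist, uncon$dist),
                     tolerance = 1e-9)
        expect_null(r$mip)
      }
    }
  }
})

test_that("mechanisms of mutually disconnected nodes are reducible", {
  x <- disconnected_pair() # {A,B} flip-flop, C self-NOT
  r <- mechanism_phi(x, c("A", "C"), c(0, 1), "effect")
  expect_equal(r$phi, 0)
  r2 <- mechanism_phi(x, c("B", "C"), c(1, 0), "cause")
  expect_equal(r2$phi, 0)
})

test_that("phi matches an independent brute-force search", {
  # all deterministic 2-node systems, both directions, pair mechanism
  for (x in all_deterministic_2node()[seq(1, 256, by = 17)]) {
    st <- index_state(1 + state_index(c(0, 1)) %% 4, 2)[1, ]
    for (dir in c("cause", "effect")) {
      got <- suppressWarnings(mechanism_phi(x, 1:2, st, dir)$phi)
      want <- suppressWarnings(oracle_phi(x, 1:2, st, dir))
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
  # the example system, every subset, both directions
  state <- c(0, 1, 1)
  for (s in all_subsets(3)) {
    for (dir in c("cause", "effect")) {
      got <- mechanism_phi(mcx, s, state[s], dir)$phi
      expect_equal(got, oracle_phi(mcx, s, state[s], dir), tolerance = 1e-9,
                   label = paste(dir, paste(s, collapse = "")))
    }
  }
})

test_that("phi is nonnegative and unchanged by unconstrained purview nodes", {
  state <- c(0, 1, 1)
  for (s in all_subsets(3)) {
    for (dir in c("cause", "effect")) {
      r <- mechanism_phi(mcx, s, state[s], dir)
      expect_gte(r$phi, 0)
      # recompute over the effective purview only: the divergence of the
      # intact repertoire restricted to constrained nodes is unchanged
      if (length(r$effective_purview) > 0 &&
          length(r$effective_purview) < 3 && length(s) == 1) {
        intact_sub <- if (dir == "effect") {
          effect_repertoire(mcx, s, state[s], r$effective_purview)
        } else {
          cause_repertoire(mcx, s, state[s], r$effective_purview)
        }
        uncon_sub <- unconstrained_repertoire(mcx, dir, r$effective_purview)
        expect_equal(kld_bits(intact_sub$dist, uncon_sub$dist), r$phi,
                     tolerance = 1e-6)
      }
    }
  }
})

test_that("composition sums the per-subset phi values", {
  comp <- composition(mcx, "011")
  expect_equal(nrow(comp$table), 14) # 7 subsets x 2 directions
  g <- glance(comp)
  expect_equal(g$sum_phi_c, 5 + log2(4 / 3), tolerance = 1e-6)
  expect_equal(g$total, comp$sum_phi_c + comp$sum_phi_e)
  # tidy() returns the long table; autoplot builds without error
  expect_s3_class(tidy(comp), "tbl_df")
  p <- autoplot(comp)
  expect_s3_class(p, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p))
  # fully disconnected nodes: all multi-node subsets reducible
  iso <- build_tpm(list(A = function(s) 1 - s[1], B = function(s) s[2],
                        C = function(s) 1 - s[3]))
  ci <- composition(iso, "101")
  multi <- ci$table[ci$table$order > 1, ]
  expect_true(all(multi$phi == 0))
})
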