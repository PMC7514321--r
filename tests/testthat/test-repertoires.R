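test_that("effect repertoires reproduce the worked single-mechanism values", {
  # C=1 makes M more likely on: 3 of the 4 completions of (M, X) give majority
  r <- effect_repertoire(mcx, "C", 1, "M")
  expect_equal(r$dist, c(0.25, 0.75))
  # C=1 does not constrain C or X at all
  r2 <- effect_repertoire(mcx, "C", 1, c("C", "X"))
  expect_equal(r2$dist, rep(0.25, 4))
  # the full mechanism over the full purview is the deterministic row
  r3 <- effect_repertoire(mcx, c("M", "C", "X"), c(0, 1, 1), c("M", "C", "X"))
  expect_equal(r3$dist, unname(state_by_state(mcx)[state_index(c(0, 1, 1)), ]))
  expect_equal(which(r3$dist == 1), state_index(c(1, 0, 1)))
})

test_that("cause repertoires invert the mechanisms under a uniform prior", {
  # M=0: the four prior states with fewer than two on-nodes, equally likely
  r <- cause_repertoire(mcx, "M", 0, c("M", "C", "X"))
  counts <- rowSums(state_grid(3))
  expect_equal(r$dist, ifelse(counts < 2, 0.25, 0))
  # MC=(0,1) pins the prior state to (1,0,0)
  r2 <- cause_repertoire(mcx, c("M", "C"), c(0, 1), c("M", "C", "X"))
  expect_equal(which(r2$dist == 1), state_index(c(1, 0, 0)))
  # CX=(1,1) pins MC_{t-1} to (1,0)
  r3 <- cause_repertoire(mcx, c("C", "X"), c(1, 1), c("M", "C"))
  expect_equal(which(r3$dist == 1), state_index(c(1, 0)))
})

test_that("unconstrained repertoires are uniform (cause) / marginal products (effect)", {
  u <- unconstrained_repertoire(mcx, "cause", c("M", "X"))
  expect_equal(u$dist, rep(0.25, 4))
  ue <- unconstrained_repertoire(mcx, "effect", "M")
  expect_equal(ue$dist, c(0.5, 0.5)) # majority on for 4 of 8 prior states
  ue3 <- unconstrained_repertoire(mcx, "effect", c("M", "C", "X"))
  expect_equal(ue3$dist, rep(1 / 8, 8)) # all three nodes have marginal 1/2
  # the empty mechanism reproduces the unconstrained repertoires
  expect_equal(effect_repertoire(mcx, integer(0), integer(0), "M")$dist,
               ue$dist)
  expect_equal(cause_repertoire(mcx, integer(0), integer(0), c("M", "X"))$dist,
               u$dist)
})

test_that("the literal-summation oracle agrees on every mechanism x purview", {
  subsets <- all_subsets(3)
  state <- c(0, 1, 1)
  for (mech in subsets) {
    for (purview in subsets) {
      for (dir in c("cause", "effect")) {
        fast <- if (dir == "effect") {
          effect_repertoire(mcx, mech, state[mech], purview)
        } else {
          cause_repertoire(mcx, mech, state[mech], purview)
        }
        slow <- brute_force_repertoire(mcx, mech, state[mech], purview, dir)
        expect_equal(fast$dist, slow$dist, tolerance = 1e-9)
      }
    }
  }
})

test_that("subset repertoires reduce to the whole-system conditionals", {
  # whole-system mechanism and purview: effect = TPM row, cause = Bayesian
  # inversion of the column under a uniform prior
  systems <- c(
    all_deterministic_2node()[seq(1, 256, by = 8)],
    lapply(1:20, function(k) sample_probabilistic_tpm(3, seed = 500 + k))
  )
  for (x in systems) {
    n <- x$n_nodes
    sbs <- state_by_state(x)
    B <- state_grid(n)
    for (r in seq_len(nrow(B))) {
      st <- B[r, ]
      eff <- effect_repertoire(x, seq_len(n), st, seq_len(n))
      expect_equal(eff$dist, unname(sbs[r, ]), tolerance = 1e-9)
      col <- sbs[, r]
      if (sum(col) > 0) {
        cau <- cause_repertoire(x, seq_len(n), st, seq_len(n))
        expect_equal(cau$dist, unname(col / sum(col)), tolerance = 1e-9)
      }
    }
  }
})

test_that("repertoires are normalized, effects factorize, causes need not", {
  for (k in 1:10) {
    x <- sample_probabilistic_tpm(3, seed = 600 + k)
    st <- index_state(1 + (k %% 8), 3)[1, ]
    for (mech in all_subsets(3)) {
      e <- effect_repertoire(x, mech, st[mech], 1:3)
      c_ <- cause_repertoire(x, mech, st[mech], 1:3)
      expect_equal(sum(e$dist), 1, tolerance = 1e-9)
      expect_equal(sum(c_$dist), 1, tolerance = 1e-9)
      # effect side: the joint is the product of its own marginals
      marg <- lapply(1:3, function(i) {
        idx <- state_grid(3)[, i]
        c(sum(e$dist[idx == 0]), sum(e$dist[idx == 1]))
      })
      prod_dist <- as.vector(outer(
        outer(marg[[1]], marg[[2]]), marg[[3]]))
      expect_equal(e$dist, prod_dist, tolerance = 1e-9)
    }
  }
  # cause repertoires generally do not factorize: MC=(0,1) is one-hot on
  # (1,0,0) but its M and C marginals are degenerate only jointly
  r <- cause_repertoire(mcx, c("M", "X"), c(0, 1), c("M", "C", "X"))
  margM <- sum(r$dist[state_grid(3)[, 1] == 1])
  margC <- sum(r$dist[state_grid(3)[, 2] == 1])
  margX <- sum(r$dist[state_grid(3)[, 3] == 1])
  prod_dist <- as.vector(outer(outer(c(1 - margM, margM), c(1 - margC, margC)),
                               c(1 - margX, margX)))
  expect_gt(max(abs(r$dist - prod_dist)), 0.1)
})

test_that("virtualised repertoires differ from plain conditionals", {
  # pi(Z|x) != p(Z|x) in general: compare the effect repertoire of a
  # mechanism with the plain conditional from the joint matrix
  x <- sample_probabilistic_tpm(3, seed = 777)
  pi_e <- effect_repertoire(x, 1, 1, c(1, 2, 3))$dist
  plain <- condition_and_marginalize(x, c(A = 1), c("A", "B", "C"))
  expect_gt(max(abs(pi_e - unname(plain))), 1e-6)
})

test_that("unreachable mechanism states yield a flagged undefined cause repertoire", {
  # node B is constant off, so B=1 is unreachable from every prior state
  x <- build_tpm(list(A = function(s) s[2], B = function(s) 0))
  expect_warning(r <- cause_repertoire(x, "B", 1, c("A", "B")), "unreachable")
  expect_true(r$undefined)
  expect_warning(rb <- brute_force_repertoire(x, "B", 1, c("A", "B"), "cause"),
                 "unreachable")
  expect_true(rb$undefined)
})
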