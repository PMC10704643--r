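test_that("with enough beams GMBS equals the exact posterior argmax", {
  for (seed in 1:6) {
    inst <- random_instance(400 + seed, nb = 2, k = 1,
                            Dbar = sample(1:3, 1), N = 4)
    bf <- enumerate_bruteforce(inst$logphi, inst$model)
    exact <- bf$sequences[[which.max(bf$log_pkx)]]
    g <- gmbs_decode(inst$logphi, inst$model, beams = 64)
    expect_identical(g$kmers, as.integer(exact))
    # with no pruning the winning beam's mass is the clamped likelihood
    expect_equal(g$log_mass,
                 forward_clamped(inst$logphi, exact, inst$model)$log_likelihood,
                 tolerance = 1e-9)
  }
})

test_that("any decode returns a shift-valid sequence with positive posterior", {
  inst <- random_instance(77, nb = 4, k = 2, Dbar = 2, N = 8)
  for (B in c(1, 4, 16)) {
    g <- gmbs_decode(inst$logphi, inst$model, beams = B)
    # sequence_from_kmers() inside gmbs_decode already validates the overlap
    expect_identical(nchar(g$sequence), length(g$kmers) + 1L)
    expect_gt(sequence_posterior(inst$logphi, g$kmers, inst$model), 0)
  }
})

test_that("beam pruning keeps the top-B by mass, stable on ties", {
  mk <- function(total, id) list(node = id, duration_mass = c(total / 2, total / 2))
  beams <- list(mk(1, 1), mk(3, 2), mk(2, 3), mk(3, 4), mk(0.5, 5))
  pruned <- prune_beams(beams, 3)
  expect_identical(vapply(pruned, `[[`, numeric(1), "node"), c(2, 3, 4))
  expect_identical(prune_beams(beams, 10), beams)
  expect_identical(length(prune_beams(beams, 2)), 2L)
  # equal masses keep insertion order
  eq <- list(mk(1, 1), mk(1, 2), mk(1, 3))
  expect_identical(vapply(prune_beams(eq, 2), `[[`, numeric(1), "node"),
                   c(1, 2))
})

test_that("the beam tree backtracks correctly and respects the size bound", {
  inst <- random_instance(55, nb = 4, k = 1, Dbar = 2, N = 12)
  B <- 8
  g <- gmbs_decode(inst$logphi, inst$model, beams = B, return_tree = TRUE)
  expect_identical(backtrack_tree(g$tree, 1L), integer(0)) # root: empty prefix
  expect_identical(backtrack_tree(g$tree, g$leaf), g$kmers)
  expect_lte(g$n_nodes, nrow(inst$logphi) * B + 1L)
  expect_error(backtrack_tree(g$tree, g$n_nodes + 10L), "dangling")
  # a hand-built 3-node chain
  tr <- edcall:::new_beam_tree(4)
  n1 <- edcall:::tree_add_nodes(tr, 1L, 2L)
  n2 <- edcall:::tree_add_nodes(tr, n1, 3L)
  n3 <- edcall:::tree_add_nodes(tr, n2, 1L)
  expect_identical(backtrack_tree(tr, n3), c(2L, 3L, 1L))
})

test_that("more beams do not hurt: B = 64 beats B = 1 on noisy reads", {
  m <- sim_model_k3(sigma = 0.33)
  id1 <- numeric(100)
  id64 <- numeric(100)
  for (i in 1:100) {
    r <- simulate_read(m, seed = 8000 + i, length_mode = "fixed", M = 30)
    lp <- score_matrix(m$observation, r$signal)
    truth <- sequence_from_kmers(r$truth_kmers, m$alphabet)
    id1[i] <- align_and_score(gmbs_decode(lp, m, beams = 1)$sequence,
                              truth)$identity
    id64[i] <- align_and_score(gmbs_decode(lp, m, beams = 64)$sequence,
                               truth)$identity
  }
  expect_gte(stats::median(id64), stats::median(id1))
})

test_that("degenerate decodes fail loudly", {
  inst <- random_instance(66, nb = 2, k = 1, Dbar = 2, N = 4)
  lp <- inst$logphi
  lp[2, ] <- -Inf # a sample no k-mer can explain
  expect_error(gmbs_decode(lp, inst$model, beams = 4), "zero mass")
})
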