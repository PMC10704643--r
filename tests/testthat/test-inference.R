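test_that("forward, clamped sum and Viterbi agree with exhaustive enumeration", {
  insts <- oracle_instances(8L)
  for (inst in insts) {
    m <- inst$model
    lp <- inst$logphi
    bf <- enumerate_bruteforce(lp, m)
    ll <- forward_free(lp, m)$log_likelihood
    expect_equal(ll, bf$log_px, tolerance = 1e-9)
    # sum over all clamped sequences recovers the free-running likelihood
    lls <- vapply(bf$sequences, function(ks)
      forward_clamped(lp, ks, m)$log_likelihood, numeric(1))
    mx <- max(lls)
    expect_equal(mx + log(sum(exp(lls - mx))), bf$log_px, tolerance = 1e-9)
    # per-sequence clamped likelihoods match the oracle table
    expect_equal(lls, bf$log_pkx, tolerance = 1e-9)
    vt <- viterbi_joint(lp, m)
    expect_identical(vt$kmers, as.integer(bf$map$kmers))
    expect_identical(vt$durations, as.integer(bf$map$durations))
    expect_equal(vt$log_joint, bf$map$log_joint, tolerance = 1e-9)
    expect_lte(vt$log_joint, ll + 1e-12)
    expect_identical(sum(vt$durations), nrow(lp))
  }
})

test_that("free-running likelihood scales linearly in any one sample's scores", {
  inst <- random_instance(5, nb = 4, k = 1, Dbar = 3, N = 6)
  ll <- forward_free(inst$logphi, inst$model)$log_likelihood
  lp2 <- inst$logphi
  lp2[3, ] <- lp2[3, ] + log(2.5)
  expect_equal(forward_free(lp2, inst$model)$log_likelihood, ll + log(2.5),
               tolerance = 1e-12)
})

test_that("clamped degenerate cases have closed forms", {
  inst <- random_instance(6, nb = 2, k = 1, Dbar = 2, N = 3)
  m <- inst$model
  lp <- inst$logphi
  # more k-mers than samples: impossible
  expect_identical(forward_clamped(lp, c(1L, 2L, 1L, 2L), m)$log_likelihood,
                   -Inf)
  # M = N: unique all-ones duration assignment
  ks <- c(1L, 2L, 1L)
  tr <- m$transitions
  expected <- log(tr$xi0[1]) + log(tr$xi[1, 2]) + log(tr$xi[2, 1]) +
    3 * log(m$durations$eta[1]) + lp[1, 1] + lp[2, 2] + lp[3, 1]
  expect_equal(forward_clamped(lp, ks, m)$log_likelihood, expected,
               tolerance = 1e-12)
})

test_that("a single-sample, single-k-mer model returns the raw score", {
  ab <- kmer_alphabet(1, bases = "A")
  dm <- duration_model(2, 2, Dbar = 1, gamma = 0)
  m <- edhmm(ab, durations = dm)
  lp <- matrix(-1.234, 1, 1)
  expect_equal(forward_free(lp, m)$log_likelihood, -1.234, tolerance = 1e-12)
})

test_that("occupancy matches the path-weighted brute-force posterior", {
  inst <- random_instance(9, nb = 2, k = 1, Dbar = 2, N = 4)
  bf <- enumerate_bruteforce(inst$logphi, inst$model)
  occ <- occupancy(inst$logphi, inst$model)
  expect_equal(unname(rowSums(occ)), rep(1, 4), tolerance = 1e-9)
  expect_equal(unname(occ), unname(bf$occupancy), tolerance = 1e-9)
  expect_true(all(occ >= 0 & occ <= 1 + 1e-12))
})

test_that("clamped occupancy is confined to the clamped k-mers", {
  inst <- random_instance(12, nb = 4, k = 1, Dbar = 2, N = 6)
  ks <- c(1L, 3L, 1L)
  occ <- occupancy(inst$logphi, inst$model, kmers = ks)
  expect_equal(unname(rowSums(occ)), rep(1, 6), tolerance = 1e-9)
  expect_true(all(occ[, c(2, 4)] == 0))
})

test_that("forced alignment is the clamped argmax and partitions the read", {
  inst <- random_instance(15, nb = 2, k = 1, Dbar = 3, N = 6)
  m <- inst$model
  lp <- inst$logphi
  ks <- c(1L, 2L, 1L)
  fa <- forced_alignment(lp, ks, m)
  expect_identical(sum(fa$durations), 6L)
  expect_identical(length(fa$durations), 3L)
  expect_identical(fa$labels, rep.int(ks, fa$durations))
  # brute-force clamped argmax over duration compositions
  best <- -Inf
  best_comp <- NULL
  for (d1 in 1:4) for (d2 in 1:(5 - d1)) {
    d3 <- 6 - d1 - d2
    comp <- c(d1, d2, d3)
    w <- log(m$transitions$xi0[1]) + log(m$transitions$xi[1, 2]) +
      log(m$transitions$xi[2, 1]) +
      sum(log(duration_pmf(m$durations, comp))) +
      sum(lp[1:d1, 1]) + sum(lp[(d1 + 1):(d1 + d2), 2]) +
      sum(lp[(d1 + d2 + 1):6, 1])
    if (w > best) {
      best <- w
      best_comp <- comp
    }
  }
  expect_identical(fa$durations, as.integer(best_comp))
  expect_equal(fa$log_joint, best, tolerance = 1e-9)
  expect_error(forced_alignment(lp[1:2, ], ks, m), "infeasible")
})

test_that("sequence posteriors are the clamped/free ratio and sum to one", {
  inst <- random_instance(21, nb = 2, k = 1, Dbar = 2, N = 5)
  m <- inst$model
  lp <- inst$logphi
  bf <- enumerate_bruteforce(lp, m)
  posts <- vapply(bf$sequences, function(ks)
    sequence_posterior(lp, ks, m), numeric(1))
  expect_equal(sum(posts), 1, tolerance = 1e-9)
  ks <- bf$sequences[[which.max(bf$log_pkx)]]
  expect_equal(sequence_posterior(lp, ks, m),
               exp(forward_clamped(lp, ks, m)$log_likelihood -
                     forward_free(lp, m)$log_likelihood),
               tolerance = 1e-12)
})

test_that("the enumeration oracle guards its own size and counts compositions", {
  inst <- random_instance(30, nb = 2, k = 1, Dbar = 2, N = 5)
  expect_error(enumerate_bruteforce(inst$logphi, inst$model, max_paths = 10),
               "too large")
  # compositions of 5 samples into 3 k-mers: C(4, 2) = 6
  bf <- enumerate_bruteforce(inst$logphi, inst$model)
  m3 <- which(lengths(bf$sequences) == 3L)
  expect_identical(length(m3), 8L) # all binary sequences of length 3
})
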