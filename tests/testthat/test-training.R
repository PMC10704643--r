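test_that("occupancy gradients match central finite differences", {
  for (seed in 1:3) {
    set.seed(300 + seed)
    ab <- kmer_alphabet(2)
    m <- edhmm(ab, durations = duration_model(2.5, 2, 3, gamma = 0.4))
    lp <- matrix(rnorm(5 * 16), 5, 16)
    ks <- kmers_from_sequence("ACG", ab)
    expect_lt(fd_max_rel_err(function(l) score_gradients(l, m), lp), 1e-5)
    expect_lt(fd_max_rel_err(function(l) score_gradients(l, m, kmers = ks), lp),
              1e-5)
    g <- score_gradients(lp, m)
    expect_equal(unname(rowSums(g$gradient)), rep(1, 5), tolerance = 1e-9)
    gc <- score_gradients(lp, m, kmers = ks)
    occ <- occupancy(lp, m, kmers = ks)
    expect_true(all(gc$gradient[occ == 0] == 0))
  }
})

test_that("modified CML losses and gradients verify for both variants", {
  set.seed(42)
  ab <- kmer_alphabet(2)
  m <- edhmm(ab, durations = duration_model(2.5, 2, 3, gamma = 0.4))
  lp <- matrix(rnorm(5 * 16), 5, 16)
  ks <- kmers_from_sequence("ACG", ab)
  expect_lt(fd_max_rel_err(function(l)
    modified_cml_loss(l, ks, m, lambda = 0.5), lp), 1e-5)
  expect_lt(fd_max_rel_err(function(l)
    modified_cml_loss(l, ks, m, lambda = 0.5, variant = "beam", beams = 8),
    lp), 1e-5)
  # lambda = 1: plain clamped likelihood and occupancy
  r1 <- modified_cml_loss(lp, ks, m, lambda = 1)
  expect_equal(r1$loss, forward_clamped(lp, ks, m)$log_likelihood,
               tolerance = 1e-12)
  expect_equal(r1$gradient, occupancy(lp, m, kmers = ks), tolerance = 1e-12)
  # free-running loss is log p(K,X) - (1 - lambda) log p(X)
  r5 <- modified_cml_loss(lp, ks, m, lambda = 0.5)
  expect_equal(r5$loss,
               forward_clamped(lp, ks, m)$log_likelihood -
                 0.5 * forward_free(lp, m)$log_likelihood,
               tolerance = 1e-12)
  expect_error(modified_cml_loss(lp, ks, m, lambda = 2), "lambda")
})

test_that("beam variant collapses to lambda * log p(K, X) when the decode is K", {
  # a near-noiseless read makes the beam decode return the reference
  m <- sim_model_k2(sigma = 0.01)
  r <- simulate_read(m, seed = 17, length_mode = "fixed", M = 8)
  lp <- score_matrix(m$observation, r$signal)
  res <- modified_cml_loss(lp, r$truth_kmers, m, lambda = 0.5,
                           variant = "beam", beams = 16)
  expect_identical(res$kmers_bs, r$truth_kmers)
  expect_equal(res$loss,
               0.5 * forward_clamped(lp, r$truth_kmers, m)$log_likelihood,
               tolerance = 1e-9)
})

test_that("Gaussian EM increases the likelihood and recovers the means", {
  m_true <- sim_model_k2(sigma = 0.12)
  reads <- simulate_run(m_true, 50, seed = 21, length_mode = "fixed", M = 75)
  set.seed(33)
  init <- gaussian_observation(m_true$observation$mu + rnorm(16, sd = 0.35),
                               0.5, m_true$alphabet)
  m0 <- edhmm(m_true$alphabet, durations = m_true$durations,
              observation = init)
  fit <- fit_gaussian_em(reads, m0, max_iter = 15)
  expect_true(all(diff(fit$loglik_trace) >= -1e-6))
  rng <- diff(range(m_true$observation$mu))
  expect_lt(max(abs(fit$observation$mu - m_true$observation$mu)) / rng, 0.05)
})

test_that("EM degenerates gracefully on a constant single-k-mer read", {
  ab <- kmer_alphabet(1, bases = c("A", "C"))
  dm <- duration_model(2, 2, 2, gamma = 0.2)
  init <- gaussian_observation(c(0.4, 5), c(1, 1), ab)
  m <- edhmm(ab, durations = dm, observation = init)
  r <- read_record(rep(1.5, 6), truth_kmers = 1L, truth_durations = 6L)
  fit <- fit_gaussian_em(list(r), m, max_iter = 5, sigma_floor = 1e-3)
  expect_equal(fit$observation$mu[[1]], 1.5, tolerance = 1e-9)
  expect_equal(fit$observation$sigma[[1]], 1e-3, tolerance = 1e-12)
  # the unvisited k-mer keeps its initial parameters
  expect_identical(fit$observation$mu[[2]], 5)
  expect_false(fit$visited[2])
})

test_that("scorer pre-training decreases cross-entropy and learns labels", {
  m <- sim_model_k2(sigma = 1e-3)
  reads <- simulate_run(m, 10, seed = 2, length_mode = "fixed", M = 60)
  data <- lapply(reads, function(r)
    list(signal = r$signal, labels = rep.int(r$truth_kmers, r$truth_durations)))
  set.seed(1)
  init <- gaussian_observation(rnorm(16, sd = 0.5), 0.3, m$alphabet)
  pt <- pretrain_scorer(data, init, epochs = 40)
  expect_true(all(diff(pt$loss_trace) <= 1e-12))
  expect_gt(pt$accuracy, 0.9)
  # an already near-one-hot scorer has near-zero loss
  sharp <- gaussian_observation(m$observation$mu, 0.02, m$alphabet)
  pt2 <- pretrain_scorer(data, sharp, epochs = 1)
  expect_lt(pt2$loss_trace[1], 0.02)
  bad <- list(list(signal = 1:3, labels = 1:2))
  expect_error(pretrain_scorer(bad, init), "mismatch")
})
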