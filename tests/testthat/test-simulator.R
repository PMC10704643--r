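test_that("simulated reads are internally consistent and deterministic", {
  m <- sim_model_k2()
  r1 <- simulate_read(m, seed = 5, length_mode = "fixed", M = 40)
  expect_identical(length(r1$signal), sum(r1$truth_durations))
  expect_identical(length(r1$truth_kmers), 40L)
  expect_true(all(r1$truth_durations >= 1L))
  # same config and seed: byte-identical read
  r2 <- simulate_read(m, seed = 5, length_mode = "fixed", M = 40)
  expect_identical(r1, r2)
  # consecutive truth k-mers respect the shift support
  expect_silent(sequence_from_kmers(r1$truth_kmers, m$alphabet))
})

test_that("dwell draws follow the explicit head plus geometric tail", {
  dm <- duration_model(5, 2.5, 8)
  set.seed(1)
  d <- edcall:::draw_durations(dm, 20000)
  tail_bins <- 10L
  breaks <- c(seq_len(dm$Dbar + tail_bins) - 0.5, Inf)
  obs <- as.vector(table(cut(d, breaks)))
  probs <- c(duration_pmf(dm, seq_len(dm$Dbar + tail_bins - 1L)),
             dm$eta[dm$Dbar] * dm$gamma^tail_bins / (1 - dm$gamma))
  expect_equal(sum(probs), 1, tolerance = 1e-12)
  ct <- suppressWarnings(stats::chisq.test(obs, p = probs))
  expect_gt(ct$p.value, 0.01)
})

test_that("geometric length mode is truncated at one k-mer", {
  ab <- kmer_alphabet(1)
  m <- edhmm(ab, durations = duration_model(2, 2, 2),
             observation = synthetic_level_table(ab))
  set.seed(3)
  Ms <- vapply(1:300, function(i)
    length(simulate_read(m, read_alpha = 0.5)$truth_kmers), integer(1))
  expect_true(all(Ms >= 1L))
  # E[M | M >= 1] = 1 / (1 - alpha) = 2 for alpha = 0.5
  expect_lt(abs(mean(Ms) - 2), 0.3)
})

test_that("uniform-shift simulation reproduces its transition model", {
  ab <- kmer_alphabet(1)
  m <- edhmm(ab, durations = duration_model(2, 2, 3),
             observation = synthetic_level_table(ab))
  reads <- simulate_run(m, 100, seed = 1, length_mode = "fixed", M = 1001)
  tc <- empirical_transition_check(reads, ab)
  expect_identical(sum(tc$counts), 100 * 1000)
  expect_equal(unname(rowSums(tc$freq)), rep(1, 4), tolerance = 1e-12)
  expect_lt(max(abs(tc$freq - 0.25)), 0.01)
  # single-k-mer reads yield no transitions
  ones <- simulate_run(m, 3, seed = 2, length_mode = "fixed", M = 1)
  expect_identical(sum(empirical_transition_check(ones, ab)$counts), 0)
  expect_error(empirical_transition_check(list(read_record(1:3)), ab),
               "no truth")
})

test_that("dwell-time drift lengthens reads across the run", {
  ab <- kmer_alphabet(1)
  m <- edhmm(ab, durations = duration_model(3, 2.5, 6),
             observation = synthetic_level_table(ab))
  reads <- simulate_run(m, 200, seed = 4, length_mode = "fixed", M = 25,
                        depletion_rate = 0.01)
  scales <- vapply(reads, `[[`, numeric(1), "duration_scale")
  expect_equal(scales, 1.01^(0:199), tolerance = 1e-12)
  dwell <- vapply(reads, function(r) mean(r$truth_durations), numeric(1))
  expect_gt(stats::cor(seq_along(dwell), dwell, method = "spearman"), 0)
  # no drift: identical scales
  flat <- simulate_run(m, 5, seed = 4, length_mode = "fixed", M = 5)
  expect_true(all(vapply(flat, `[[`, numeric(1), "duration_scale") == 1))
})

test_that("a written run round-trips from disk", {
  m <- sim_model_k2()
  outdir <- file.path(tempdir(), "edcall-run-test")
  on.exit(unlink(outdir, recursive = TRUE))
  reads <- simulate_run(m, 4, seed = 6, length_mode = "fixed", M = 20,
                        outdir = outdir)
  expect_true(file.exists(file.path(outdir, "truth.fasta")))
  back <- read_run(outdir)
  expect_identical(length(back), 4L)
  for (i in 1:4) {
    expect_equal(back[[i]]$signal, reads[[i]]$signal, tolerance = 1e-9)
    expect_identical(back[[i]]$truth_kmers, reads[[i]]$truth_kmers)
    expect_identical(back[[i]]$truth_durations, reads[[i]]$truth_durations)
  }
})
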