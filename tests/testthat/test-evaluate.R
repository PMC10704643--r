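test_that("alignment metrics match hand alignments and identities", {
  m <- align_and_score("ACGT", "ACGT")
  expect_identical(m$identity, 1)
  expect_identical(m$edit_distance, 0L + 0L)
  m2 <- align_and_score("ACGT", "ACGA")
  expect_identical(m2$matches, 3L)
  expect_identical(m2$mismatches, 1L)
  expect_identical(m2$identity, 0.75)
  expect_error(align_and_score("", "ACGT"), "non-empty")
})

test_that("alignment distance equals the quadratic DP oracle on random pairs", {
  set.seed(99)
  for (i in 1:200) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(1:50, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(1:50, 1), TRUE),
               collapse = "")
    m <- align_and_score(a, b)
    expect_identical(m$edit_distance,
                     as.integer(utils::adist(a, b)))
    # column identity: categories partition the alignment
    expect_identical(m$matches + m$mismatches + m$insertions + m$deletions,
                     m$columns)
    expect_equal(m$identity +
                   (m$mismatches + m$insertions + m$deletions) / m$columns,
                 1, tolerance = 1e-12)
  }
})

test_that("homopolymer scoring demands the exact run length", {
  hp <- homopolymer_eval("AAAA", "AAAA", min_len = 3)
  expect_identical(c(hp$correct, hp$total), c(1L, 1L))
  expect_identical(hp$accuracy, 1)
  hp2 <- homopolymer_eval("AAA", "AAAA", min_len = 3)
  expect_identical(c(hp2$correct, hp2$total), c(0L, 1L))
  # runs shorter than min_len are not scored
  hp3 <- homopolymer_eval("CCAAC", "CCAAC", min_len = 3)
  expect_identical(hp3$total, 0L)
  # mixed case with a per-length breakdown
  hp4 <- homopolymer_eval("GGGTTTTA", "GGGTTTTTA", min_len = 3)
  expect_identical(hp4$total, 2L)
  expect_identical(hp4$correct, 1L)
  expect_equal(hp4$accuracy, 0.5)
  expect_identical(hp4$by_length$length, c(3L, 5L))
})

test_that("chunk plans tile the signal with the documented stride", {
  p <- chunk_signal(8000, L = 4096, overlap = 296)
  expect_identical(p$start, c(0L, 3800L, 7600L))
  expect_identical(p$end, c(4096L, 7896L, 8000L))
  expect_identical(chunk_signal(1000)$start, 0L)
  expect_identical(chunk_signal(1000)$end, 1000L)
  expect_error(chunk_signal(100, L = 10, overlap = 10), "overlap")
  set.seed(8)
  for (i in 1:20) {
    n <- sample(1:5000, 1)
    L <- sample(10:500, 1)
    ov <- sample(0:(L - 1L), 1)
    p <- chunk_signal(n, L, ov)
    covered <- rep(FALSE, n)
    for (j in seq_len(nrow(p))) covered[(p$start[j] + 1):p$end[j]] <- TRUE
    expect_true(all(covered))
    if (nrow(p) > 1) expect_true(all(diff(p$start) == L - ov))
  }
})

test_that("stitching removes duplicated overlaps and is exact when consistent", {
  expect_identical(stitch_sequences("ACGT"), "ACGT")
  set.seed(12)
  full <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  left <- substr(full, 1, 180)
  right <- substr(full, 161, 300) # exact 20-base overlap
  out <- stitch_sequences(c(left, right))
  expect_identical(out, full)
  # perfectly consistent multi-chunk split reproduces the original
  chunks <- c(substr(full, 1, 120), substr(full, 91, 210), substr(full, 181, 300))
  expect_identical(stitch_sequences(chunks), full)
  # no credible overlap: plain concatenation
  expect_identical(stitch_sequences(c("AAAAAAAAAA", "GTGTGTGTGT")),
                   "AAAAAAAAAAGTGTGTGTGT")
})

test_that("evaluate_basecalls pairs reads and aggregates homopolymers", {
  pred <- c(r1 = "ACGTTT", r2 = "AAAG")
  truth <- c(r2 = "AAAG", r1 = "ACGTTT")
  df <- evaluate_basecalls(pred, truth)
  expect_identical(nrow(df), 2L)
  expect_equal(df$identity, c(1, 1))
  expect_identical(df$hp_total, c(1L, 1L))
})
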