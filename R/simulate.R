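#' A raw-signal read with optional ground truth
#'
#' @param signal numeric vector of normalized current samples.
#' @param read_id read identifier string.
#' @param truth_kmers optional integer k-mer index sequence `K`.
#' @param truth_durations optional positive integer dwell sequence `D`; when
#'   both truths are present `length(signal)` must equal `sum(truth_durations)`.
#' @param duration_scale optional per-read dwell scale actually used.
#' @return object of class `read_record`.
#' @export
read_record <- function(signal, read_id = "read", truth_kmers = NULL,
                        truth_durations = NULL, duration_scale = 1) {
  signal <- as.numeric(signal)
  if (!is.null(truth_durations)) {
    truth_durations <- as.integer(truth_durations)
    if (any(truth_durations < 1L)) stopf("durations must be >= 1")
  }
  if (!is.null(truth_kmers) && !is.null(truth_durations)) {
    if (length(truth_kmers) != length(truth_durations)) {
      stopf("truth k-mer and duration sequences differ in length")
    }
    if (length(signal) != sum(truth_durations)) {
      stopf("signal length %d != total dwell %d",
            length(signal), sum(truth_durations))
    }
  }
  structure(list(signal = signal, read_id = as.character(read_id),
                 truth_kmers = truth_kmers,
                 truth_durations = truth_durations,
                 duration_scale = duration_scale),
            class = "read_record")
}

#' @export
print.read_record <- function(x, ...) {
  cat(sprintf("read %s: %d samples%s\n", x$read_id, length(x$signal),
              if (!is.null(x$truth_kmers))
                sprintf(", truth: %d k-mers", length(x$truth_kmers)) else ""))
  invisible(x)
}

draw_durations <- function(dm, M) {
  # explicit head by inverse CDF, geometric tail via rgeom
  head_cum <- cumsum(dm$eta_entry)
  u <- stats::runif(M)
  d <- findInterval(u, head_cum) + 1L
  in_tail <- d >= dm$Dbar
  if (any(in_tail)) {
    d[in_tail] <- dm$Dbar + stats::rgeom(sum(in_tail), prob = 1 - dm$gamma)
  }
  as.integer(d)
}

#' Simulate one nanopore read from the generative model
#'
#' Draws the k-mer count `M` (geometric with continuation probability
#' `read_alpha`, truncated at `M >= 1`, or fixed), the k-mer chain from the
#' transition model, i.i.d. dwell times from the duration model (explicit
#' head plus geometric tail, rescaled per read by `duration_scale`), and one
#' Gaussian current sample per dwell step with standard deviation scaled by
#' `noise_scale`. Ground truth is stored on the returned [read_record()].
#'
#' @param model an [edhmm()] whose observation is a [gaussian_observation()].
#' @param seed optional integer seed (same model, same seed: identical read).
#' @param length_mode `"geometric"` or `"fixed"`.
#' @param read_alpha continuation probability of the geometric length prior
#'   (mean sequence length `read_alpha / (1 - read_alpha)` before
#'   truncation).
#' @param M fixed k-mer count when `length_mode = "fixed"`.
#' @param noise_scale multiplier on the emission standard deviations.
#' @param duration_scale per-read multiplier on the dwell scale parameter.
#' @param read_id identifier for the read.
#' @return a [read_record()] with truth attached.
#' @export
simulate_read <- function(model, seed = NULL,
                          length_mode = c("geometric", "fixed"),
                          read_alpha = 0.99, M = NULL, noise_scale = 1,
                          duration_scale = 1, read_id = "read_1") {
  stopifnot(inherits(model, "edhmm"),
            inherits(model$observation, "gaussian_obs"))
  length_mode <- match.arg(length_mode)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (length_mode == "geometric") {
    if (read_alpha < 0 || read_alpha >= 1) stopf("'read_alpha' must be in [0, 1)")
    M <- 0L
    while (M < 1L) M <- stats::rgeom(1L, prob = 1 - read_alpha)
  } else {
    M <- as.integer(M)
    if (is.na(M) || M < 1L) stopf("fixed 'M' must be >= 1")
  }
  ss <- model$ss
  # k-mer chain: first from xi0, then one base per step on the shift support
  kmers <- integer(M)
  kmers[1L] <- sample.int(ss$nK, 1L, prob = model$transitions$xi0)
  if (M > 1L) {
    xiw <- exp(ss$logxi_succ)
    for (m in 2:M) {
      b <- sample.int(ss$nb, 1L, prob = xiw[kmers[m - 1L], ])
      kmers[m] <- ss$succ[kmers[m - 1L], b]
    }
  }
  dm <- if (duration_scale == 1) model$durations else
    rescale_duration(model$durations, duration_scale)
  durations <- draw_durations(dm, M)
  mu <- model$observation$mu[rep.int(kmers, durations)]
  sg <- model$observation$sigma[rep.int(kmers, durations)] * noise_scale
  signal <- stats::rnorm(length(mu), mean = mu, sd = sg)
  read_record(signal, read_id = read_id, truth_kmers = kmers,
              truth_durations = durations, duration_scale = duration_scale)
}

#' Simulate a sequencing run with optional dwell-time drift
#'
#' Simulates `n_reads` reads; read `i` (0-based) uses dwell scale
#' `(1 + depletion_rate)^i`, emulating the slow-down of translocation across
#' a run as ATP depletes. With `outdir` set, writes one single-column signal
#' file per read, the truth sequences as FASTA, and the truth alignment
#' (read id, k-mer index, duration) as TSV.
#'
#' @inheritParams simulate_read
#' @param n_reads number of reads.
#' @param depletion_rate nonnegative per-read multiplicative dwell growth
#'   (default 0: no drift).
#' @param outdir optional output directory.
#' @param ... passed to [simulate_read()] (`length_mode`, `read_alpha`, `M`,
#'   `noise_scale`).
#' @return list of [read_record()]s (invisibly carries `outdir` as an
#'   attribute when written).
#' @export
simulate_run <- function(model, n_reads, seed = NULL, depletion_rate = 0,
                         outdir = NULL, ...) {
  if (n_reads < 1L) stopf("'n_reads' must be >= 1")
  if (depletion_rate < 0) stopf("'depletion_rate' must be nonnegative")
  if (!is.null(seed)) set.seed(as.integer(seed))
  reads <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    reads[[i]] <- simulate_read(
      model, seed = NULL,
      duration_scale = (1 + depletion_rate)^(i - 1L),
      read_id = sprintf("read_%04d", i), ...)
  }
  if (!is.null(outdir)) {
    write_run(reads, outdir, model$alphabet)
    attr(reads, "outdir") <- outdir
  }
  reads
}

#' @export
simulate.edhmm <- function(object, nsim = 1, seed = NULL, ...) {
  simulate_run(object, n_reads = nsim, seed = seed, ...)
}

#' Empirical k-mer transition frequencies of simulated truth
#'
#' Tabulates consecutive truth k-mer pairs across reads, a self-test that
#' the simulator follows its transition model.
#'
#' @param reads list of [read_record()]s with truth.
#' @param alphabet the [kmer_alphabet()].
#' @return list with `counts` (`size x size` matrix) and `freq` (rows
#'   normalized where observed, `NaN` elsewhere).
#' @export
empirical_transition_check <- function(reads, alphabet) {
  nK <- alphabet$size
  counts <- matrix(0, nK, nK, dimnames = list(alphabet$kmers, alphabet$kmers))
  for (r in reads) {
    if (is.null(r$truth_kmers)) stopf("read %s has no truth", r$read_id)
    k <- r$truth_kmers
    if (length(k) > 1L) {
      from <- k[-length(k)]
      to <- k[-1L]
      tab <- tabulate((from - 1L) * nK + to, nbins = nK * nK)
      counts <- counts + t(matrix(tab, nK, nK))
    }
  }
  freq <- counts / rowSums(counts)
  list(counts = counts, freq = freq)
}
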