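#' Uniform single-base-shift transition model
#'
#' The k-mer process advances one base per step: k-mer `K'` can follow `K`
#' only when the last `k - 1` bases of `K` equal the first `k - 1` bases of
#' `K'`. This constructor puts equal probability `1/nbases` on each of the
#' `nbases` legal successors, which avoids biasing the model towards any
#' particular genome. The initial distribution is uniform over all k-mers.
#'
#' @param alphabet a [kmer_alphabet()].
#' @param exclude_self drop the self-shift of homopolymer k-mers (a
#'   homopolymer extending itself leaves the current level unchanged, so the
#'   split between one long dwell and several short ones is unidentifiable
#'   from the signal; excluding it gives a chain where every transition
#'   moves the level, useful for exactness studies). Default `FALSE`.
#' @return An object of class `kmer_transitions`: list with `xi0` (initial
#'   probabilities, length `size`), `xi` (row-stochastic `size x size`
#'   matrix) and `mode`.
#' @export
uniform_shift_transitions <- function(alphabet, exclude_self = FALSE) {
  nK <- alphabet$size
  sh <- shift_successors(alphabet)
  xi <- matrix(0, nK, nK, dimnames = list(alphabet$kmers, alphabet$kmers))
  p <- 1 / alphabet$nbases
  for (b in seq_len(alphabet$nbases)) {
    xi[cbind(seq_len(nK), sh$succ[, b])] <- xi[cbind(seq_len(nK), sh$succ[, b])] + p
  }
  if (exclude_self) {
    if (alphabet$nbases < 2L) stopf("'exclude_self' needs at least 2 bases")
    diag(xi) <- 0
    xi <- xi / rowSums(xi)
  }
  new_transitions(rep(1 / nK, nK), xi, "uniform_shift", alphabet)
}

#' Estimate shift transitions by frequency counting on a reference
#'
#' Maximum-likelihood (bigram counting) estimate of the k-mer transition
#' matrix from a reference sequence, restricted to the single-base-shift
#' support. A pseudocount can be added on the support; rows never observed
#' fall back to the uniform shift distribution.
#'
#' @param seq reference base string of length at least `k + 1`.
#' @param alphabet a [kmer_alphabet()].
#' @param pseudocount nonnegative value added to every legal transition.
#' @return A `kmer_transitions` object (`mode = "reference_counts"`); `xi0` is
#'   the empirical k-mer frequency in the reference.
#' @export
count_transitions_from_reference <- function(seq, alphabet, pseudocount = 0) {
  if (pseudocount < 0) stopf("'pseudocount' must be nonnegative")
  if (nchar(seq) < alphabet$k + 1L) stopf("reference shorter than k + 1 bases")
  idx <- kmers_from_sequence(seq, alphabet)
  nK <- alphabet$size
  from <- idx[-length(idx)]
  to <- idx[-1L]
  # bigram counts, stored column-major as (to, from) then transposed
  counts <- matrix(tabulate((from - 1L) * nK + to, nbins = nK * nK), nK, nK)
  counts <- t(counts)
  sh <- shift_successors(alphabet)
  support <- matrix(FALSE, nK, nK)
  support[cbind(rep(seq_len(nK), alphabet$nbases), as.vector(sh$succ))] <- TRUE
  counts[support] <- counts[support] + pseudocount
  counts[!support] <- 0
  rs <- rowSums(counts)
  xi <- counts
  zero <- rs == 0
  if (any(!zero)) xi[!zero, ] <- counts[!zero, , drop = FALSE] / rs[!zero]
  if (any(zero)) xi[zero, ] <- support[zero, , drop = FALSE] / alphabet$nbases
  xi0 <- tabulate(idx, nbins = nK)
  xi0 <- xi0 / sum(xi0)
  dimnames(xi) <- list(alphabet$kmers, alphabet$kmers)
  new_transitions(xi0, xi, "reference_counts", alphabet)
}

new_transitions <- function(xi0, xi, mode, alphabet) {
  stopifnot(abs(sum(xi0) - 1) < 1e-9, all(abs(rowSums(xi) - 1) < 1e-9))
  structure(list(xi0 = xi0, xi = xi, mode = mode, k = alphabet$k),
            class = "kmer_transitions")
}

#' @export
print.kmer_transitions <- function(x, ...) {
  cat(sprintf("k-mer transition model (%s): %d x %d, %d nonzero entries\n",
              x$mode, nrow(x$xi), ncol(x$xi), sum(x$xi > 0)))
  invisible(x)
}
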