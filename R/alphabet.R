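#' k-mer alphabet
#'
#' Builds the state alphabet of all length-`k` strings over a base set. The
#' index/string mapping is big-endian positional encoding in the declared base
#' order (with the default DNA bases, `A` = digit 0, `C` = 1, `G` = 2,
#' `T` = 3), so for `k = 2` the k-mer `"AC"` has digit value 1 and sits at
#' R index 2. Non-nucleotide base sets (any >= 1 distinct single characters)
#' are supported so that exhaustive test instances stay small.
#'
#' @param k k-mer length (positive integer).
#' @param bases character vector of distinct single-character symbols, in
#'   digit order. Default `c("A","C","G","T")`.
#' @return An object of class `kmer_alphabet`: a list with `k`, `bases`,
#'   `nbases`, `size` (`nbases^k`) and `kmers` (all k-mer strings in index
#'   order).
#' @examples
#' ab <- kmer_alphabet(2)
#' ab$size              # 16
#' ab$kmers[2]          # "AC"
#' @export
kmer_alphabet <- function(k, bases = c("A", "C", "G", "T")) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stopf("'k' must be a positive integer")
  bases <- as.character(bases)
  if (length(bases) < 1L || anyDuplicated(bases) || any(!nzchar(bases)) ||
      any(nchar(bases) != 1L)) {
    stopf("'bases' must be distinct single characters")
  }
  nb <- length(bases)
  size <- nb^k
  if (size > 2^20) stopf("alphabet too large (%d k-mers)", size)
  # digits big-endian: first position most significant
  idx <- 0:(size - 1L)
  mat <- matrix("", size, k)
  v <- idx
  for (j in k:1) {
    mat[, j] <- bases[v %% nb + 1L]
    v <- v %/% nb
  }
  kmers <- do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
  structure(
    list(k = k, bases = bases, nbases = nb, size = as.integer(size),
         kmers = kmers),
    class = "kmer_alphabet"
  )
}

#' @export
print.kmer_alphabet <- function(x, ...) {
  cat(sprintf("k-mer alphabet: k = %d over {%s} (%d states)\n",
              x$k, paste(x$bases, collapse = ","), x$size))
  invisible(x)
}

base_codes <- function(seq, alphabet) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  code <- match(ch, alphabet$bases)
  if (anyNA(code)) {
    stopf("unknown symbol '%s' in sequence", ch[which(is.na(code))[1]])
  }
  code - 1L
}

#' Encode a base sequence as overlapping k-mer indices
#'
#' Slides a window of width `k` along `seq` and returns the 1-based index of
#' each k-mer, so a sequence of `L` bases yields `M = L - k + 1` indices whose
#' consecutive entries always satisfy the single-base-shift overlap.
#'
#' @param seq a single base string.
#' @param alphabet a [kmer_alphabet()].
#' @return integer vector of k-mer indices (length `nchar(seq) - k + 1`).
#' @examples
#' ab <- kmer_alphabet(2)
#' kmers_from_sequence("ACGT", ab) - 1L  # big-endian values 1, 6, 11
#' @export
kmers_from_sequence <- function(seq, alphabet) {
  if (!is.character(seq) || length(seq) != 1L) stopf("'seq' must be one string")
  k <- alphabet$k
  if (nchar(seq) < k) stopf("sequence shorter than k = %d", k)
  code <- base_codes(seq, alphabet)
  M <- length(code) - k + 1L
  val <- numeric(M)
  nb <- alphabet$nbases
  for (j in 1:k) {
    val <- val * nb + code[j:(j + M - 1L)]
  }
  as.integer(val + 1L)
}

#' Decode a k-mer index path back into a base sequence
#'
#' Inverse of [kmers_from_sequence()]: the first k-mer contributes `k` bases
#' and every subsequent k-mer contributes its final base. Consecutive k-mers
#' must agree on their `k - 1` base overlap.
#'
#' @param kmers integer vector of 1-based k-mer indices.
#' @param alphabet a [kmer_alphabet()].
#' @return a base string of length `length(kmers) + k - 1`.
#' @export
sequence_from_kmers <- function(kmers, alphabet) {
  kmers <- as.integer(kmers)
  if (length(kmers) < 1L) stopf("empty k-mer path")
  if (any(kmers < 1L | kmers > alphabet$size)) stopf("k-mer index out of range")
  nb <- alphabet$nbases
  k <- alphabet$k
  if (length(kmers) > 1L) {
    prev <- kmers[-length(kmers)] - 1L
    cur <- kmers[-1L] - 1L
    if (any(prev %% nb^(k - 1L) != cur %/% nb)) {
      stopf("inconsistent path: consecutive k-mers do not overlap by k-1 bases")
    }
  }
  first <- alphabet$kmers[kmers[1L]]
  if (length(kmers) == 1L) return(first)
  last_base <- alphabet$bases[(kmers[-1L] - 1L) %% nb + 1L]
  paste0(first, paste(last_base, collapse = ""))
}

# Successor/predecessor index matrices under the single-base-shift rule.
# succ[K, b] appends base b to K (dropping its first base); pred[K, b] is the
# k-mer whose shift by the last base of K gives K, with leading base b.
shift_successors <- function(alphabet) {
  nK <- alphabet$size
  nb <- alphabet$nbases
  hi <- nb^(alphabet$k - 1L)
  K <- 0:(nK - 1L)
  succ <- outer(K %% hi * nb, 0:(nb - 1L), `+`) + 1L
  pred <- outer(K %/% nb, (0:(nb - 1L)) * hi, `+`) + 1L
  storage.mode(succ) <- "integer"
  storage.mode(pred) <- "integer"
  list(succ = succ, pred = pred)
}
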