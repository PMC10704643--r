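# Alignment-based accuracy metrics. The identity score of a basecalled read
# is the ratio of matched bases to total alignment columns of a
# minimum-edit (Levenshtein) global alignment:
#   identity = matches / (matches + mismatches + insertions + deletions).

edit_submat <- function(chars) {
  m <- matrix(-1, length(chars), length(chars),
              dimnames = list(chars, chars))
  diag(m) <- 0
  m
}

#' Align a basecall to its truth and score it
#'
#' Computes a global minimum-edit alignment (unit costs for mismatches and
#' gaps, via [Biostrings::pairwiseAlignment()] with a 0/-1 substitution
#' matrix and gap cost 1) and counts alignment columns per category.
#' Insertions are pred bases absent from truth (gap in truth); deletions are
#' truth bases absent from pred.
#'
#' @param pred basecalled sequence (non-empty string).
#' @param truth reference/truth sequence (non-empty string).
#' @return list of class `alignment_metrics`: `matches`, `mismatches`,
#'   `insertions`, `deletions`, `columns`, `identity`, `edit_distance`, and
#'   the aligned strings `aligned_pred` / `aligned_truth` (with `-` gaps).
#' @export
align_and_score <- function(pred, truth) {
  if (!nzchar(pred) || !nzchar(truth)) stopf("sequences must be non-empty")
  chars <- sort(unique(strsplit(paste0(pred, truth), "")[[1]]))
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::BString(pred), subject = Biostrings::BString(truth),
    substitutionMatrix = edit_submat(chars),
    gapOpening = 0, gapExtension = 1, type = "global")
  ap <- as.character(Biostrings::alignedPattern(pa))
  at <- as.character(Biostrings::alignedSubject(pa))
  pc <- strsplit(ap, "")[[1]]
  tc <- strsplit(at, "")[[1]]
  ins <- sum(tc == "-")
  del <- sum(pc == "-")
  match <- sum(pc == tc)
  mism <- length(pc) - ins - del - match
  structure(list(
    matches = match, mismatches = mism, insertions = ins, deletions = del,
    columns = length(pc),
    identity = match / length(pc),
    edit_distance = mism + ins + del,
    aligned_pred = ap, aligned_truth = at
  ), class = "alignment_metrics")
}

#' @export
print.alignment_metrics <- function(x, ...) {
  cat(sprintf(
    "alignment: identity %.4f (%d match / %d mismatch / %d ins / %d del over %d columns)\n",
    x$identity, x$matches, x$mismatches, x$insertions, x$deletions, x$columns))
  invisible(x)
}

#' Homopolymer basecalling accuracy
#'
#' Scores every maximal run of identical bases in the truth with length at
#' least `min_len`. A run counts as correct iff the pred bases aligned to the
#' run's alignment columns (gaps removed, including insertion columns inside
#' the run) reproduce exactly the same base with the same run length.
#'
#' @param pred basecalled sequence.
#' @param truth truth sequence.
#' @param min_len minimum run length scored (default 3).
#' @param metrics optional precomputed [align_and_score()] result for this
#'   pair.
#' @return list of class `homopolymer_report`: `correct`, `total`,
#'   `accuracy` and `by_length` (data frame with per-length counts).
#' @export
homopolymer_eval <- function(pred, truth, min_len = 3L,
                             metrics = NULL) {
  if (min_len < 2L) stopf("'min_len' must be >= 2")
  if (is.null(metrics)) metrics <- align_and_score(pred, truth)
  pc <- strsplit(metrics$aligned_pred, "")[[1]]
  tc <- strsplit(metrics$aligned_truth, "")[[1]]
  # map truth positions to alignment columns
  tpos_col <- which(tc != "-")
  tseq <- tc[tpos_col]
  r <- rle(tseq)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_len
  lens <- r$lengths[keep]
  total <- sum(keep)
  correct_flag <- logical(total)
  if (total > 0L) {
    ks <- starts[keep]
    ke <- ends[keep]
    for (i in seq_len(total)) {
      cols <- tpos_col[ks[i]]:tpos_col[ke[i]]
      seg <- pc[cols]
      seg <- seg[seg != "-"]
      correct_flag[i] <- length(seg) == lens[i] && all(seg == r$values[keep][i])
    }
  }
  by_length <- if (total > 0L) {
    agg <- stats::aggregate(correct_flag, by = list(length = lens), FUN = sum)
    cnt <- as.data.frame(table(length = lens), stringsAsFactors = FALSE)
    data.frame(length = agg$length, total = as.integer(cnt$Freq),
               correct = as.integer(agg$x),
               accuracy = agg$x / cnt$Freq)
  } else {
    data.frame(length = integer(0), total = integer(0), correct = integer(0),
               accuracy = numeric(0))
  }
  structure(list(correct = sum(correct_flag), total = total,
                 accuracy = if (total > 0L) sum(correct_flag) / total else NA_real_,
                 by_length = by_length),
            class = "homopolymer_report")
}

#' @export
print.homopolymer_report <- function(x, ...) {
  cat(sprintf("homopolymers: %d/%d correct (accuracy %.3f)\n",
              x$correct, x$total, x$accuracy))
  invisible(x)
}

#' Plan overlapping chunks of a raw signal
#'
#' Long reads are decoded in fixed-length segments for bounded memory;
#' defaults follow the production setting of 4096-sample chunks overlapping
#' by 296 samples. Windows are 0-based half-open `[start, end)`, consecutive
#' starts differ by `L - overlap`, and their union covers every sample.
#'
#' @param n signal length (or a numeric signal vector).
#' @param L chunk length in samples.
#' @param overlap overlap between consecutive chunks (`0 <= overlap < L`).
#' @return object of class `chunk_plan`: data frame with columns `start`,
#'   `end` (0-based half-open).
#' @export
chunk_signal <- function(n, L = 4096L, overlap = 296L) {
  if (length(n) > 1L) n <- length(n)
  n <- as.integer(n)
  L <- as.integer(L)
  overlap <- as.integer(overlap)
  if (n < 1L) stopf("empty signal")
  if (overlap < 0L || L <= overlap) stopf("need L > overlap >= 0")
  stride <- L - overlap
  starts <- 0L
  while (starts[length(starts)] + L < n) {
    starts <- c(starts, starts[length(starts)] + stride)
  }
  plan <- data.frame(start = starts, end = pmin(starts + L, n))
  class(plan) <- c("chunk_plan", "data.frame")
  plan
}

#' Stitch per-chunk basecalls into one sequence
#'
#' Consecutive chunk outputs share the bases called from the overlapping
#' samples. For each consecutive pair, the suffix of the left output is
#' aligned to the prefix of the right output with an ends-free overlap
#' alignment; the pair is cut at the aligned junction (overlap bases kept
#' once, from the left output). Pairs with no credible overlap (alignment
#' score below `min_score` matches) are concatenated directly.
#'
#' @param chunk_outputs character vector of per-chunk sequences, in order.
#' @param window number of terminal bases of each side searched for the
#'   overlap.
#' @param min_score minimum overlap alignment score (2/-3 match/mismatch,
#'   gap open 4, gap extend 2) to accept a junction.
#' @return the stitched sequence string.
#' @export
stitch_sequences <- function(chunk_outputs, window = 200L, min_score = 8) {
  chunk_outputs <- chunk_outputs[nzchar(chunk_outputs)]
  if (length(chunk_outputs) == 0L) return("")
  out <- chunk_outputs[1L]
  for (i in seq_along(chunk_outputs)[-1L]) {
    right <- chunk_outputs[i]
    nl <- nchar(out)
    wl <- min(window, nl)
    wr <- min(window, nchar(right))
    tl <- substr(out, nl - wl + 1L, nl)
    hr <- substr(right, 1L, wr)
    ch <- sort(unique(strsplit(paste0(tl, hr), "")[[1]]))
    sm <- matrix(-3, length(ch), length(ch), dimnames = list(ch, ch))
    diag(sm) <- 2
    pa <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::BString(tl), subject = Biostrings::BString(hr),
      substitutionMatrix = sm,
      gapOpening = 4, gapExtension = 2, type = "overlap")
    if (Biostrings::score(pa) < min_score) {
      out <- paste0(out, right)
    } else {
      # keep the left output up to the end of its aligned region, then the
      # right output after its aligned region
      keep_left <- nl - wl + pa@pattern@range@start + pa@pattern@range@width - 1L
      drop_right <- pa@subject@range@start + pa@subject@range@width - 1L
      out <- paste0(substr(out, 1L, keep_left),
                    substr(right, drop_right + 1L, nchar(right)))
    }
  }
  out
}

#' Evaluate basecalls against truth sequences
#'
#' Pairs predicted and truth sequences by name (or by order when unnamed)
#' and reports per-read alignment metrics plus a homopolymer summary.
#'
#' @param pred named character vector of basecalled sequences.
#' @param truth named character vector of truth sequences.
#' @param min_hp_len minimum homopolymer length scored.
#' @return data frame with one row per read: identity, error counts and
#'   homopolymer counts; total rows can be aggregated by the caller.
#' @export
evaluate_basecalls <- function(pred, truth, min_hp_len = 3L) {
  if (!is.null(names(pred)) && !is.null(names(truth))) {
    common <- intersect(names(pred), names(truth))
    if (length(common) == 0L) stopf("no read names in common")
    pred <- pred[common]
    truth <- truth[common]
  } else if (length(pred) != length(truth)) {
    stopf("pred and truth differ in length and are unnamed")
  }
  rows <- lapply(seq_along(pred), function(i) {
    m <- align_and_score(pred[[i]], truth[[i]])
    hp <- homopolymer_eval(pred[[i]], truth[[i]], min_len = min_hp_len,
                           metrics = m)
    data.frame(read_id = names(pred)[i] %||% as.character(i),
               identity = m$identity, matches = m$matches,
               mismatches = m$mismatches, insertions = m$insertions,
               deletions = m$deletions, columns = m$columns,
               hp_correct = hp$correct, hp_total = hp$total)
  })
  do.call(rbind, rows)
}
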