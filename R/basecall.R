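#' Basecall raw signals with a fitted EDHMM
#'
#' Decodes one signal (numeric vector) or a list of signals /
#' [read_record()]s into base sequences. Signals longer than `chunk_len` are
#' split by [chunk_signal()], each chunk decoded independently, and the
#' chunk calls assembled with [stitch_sequences()]. The decoder is either
#' the duration-marginalizing beam search ([gmbs_decode()], default) or the
#' jointly-optimal Viterbi path projected to its k-mer sequence
#' ([viterbi_joint()]).
#'
#' @param object an [edhmm()] with an observation scorer.
#' @param signals numeric vector, list of numeric vectors, or list of
#'   [read_record()]s.
#' @param decoder `"gmbs"` or `"viterbi"`.
#' @param beams beam list size for GMBS.
#' @param chunk_len,chunk_overlap chunking parameters in samples (defaults
#'   4096 and 296); set `chunk_len = Inf` to force whole-read decoding.
#' @param ... unused.
#' @return named character vector of basecalled sequences.
#' @export
predict.edhmm <- function(object, signals, decoder = c("gmbs", "viterbi"),
                          beams = 512L, chunk_len = 4096L,
                          chunk_overlap = 296L, ...) {
  decoder <- match.arg(decoder)
  if (is.numeric(signals)) signals <- list(signals)
  sigs <- lapply(signals, function(s) if (inherits(s, "read_record")) s$signal else s)
  ids <- if (!is.null(names(signals))) names(signals) else
    vapply(seq_along(signals), function(i) {
      s <- signals[[i]]
      if (inherits(s, "read_record")) s$read_id else sprintf("read_%04d", i)
    }, character(1))
  calls <- vapply(sigs, function(sig) {
    basecall_signal(object, sig, decoder = decoder, beams = beams,
                    chunk_len = chunk_len, chunk_overlap = chunk_overlap)
  }, character(1))
  stats::setNames(calls, ids)
}

decode_one <- function(model, logphi, decoder, beams) {
  if (decoder == "gmbs") {
    gmbs_decode(logphi, model, beams = beams)$sequence
  } else {
    sequence_from_kmers(viterbi_joint(logphi, model)$kmers, model$alphabet)
  }
}

basecall_signal <- function(model, signal, decoder = "gmbs", beams = 512L,
                            chunk_len = 4096L, chunk_overlap = 296L) {
  n <- length(signal)
  if (n < 1L) stopf("empty signal")
  if (!is.finite(chunk_len) || n <= chunk_len) {
    lp <- model_scores(model, signal)
    return(decode_one(model, lp, decoder, beams))
  }
  plan <- chunk_signal(n, L = chunk_len, overlap = chunk_overlap)
  pieces <- vapply(seq_len(nrow(plan)), function(i) {
    seg <- signal[(plan$start[i] + 1L):plan$end[i]]
    decode_one(model, model_scores(model, seg), decoder, beams)
  }, character(1))
  stitch_sequences(pieces)
}
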