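# Plain-text dataset I/O: FASTA for sequences (via Biostrings, wrapped at
# 80 columns), single-column float text for raw signals, TSV for truth
# alignments and metrics, YAML for model configuration.

#' Read and write FASTA sequence files
#'
#' @param path file path.
#' @param seqs named character vector of sequences.
#' @return `read_fasta()` returns a named character vector (record order
#'   preserved); `write_fasta()` returns `path` invisibly.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read and write a raw signal as single-column float text
#'
#' @param path file path.
#' @param signal numeric vector.
#' @return `read_signal()` returns a numeric vector; non-numeric lines raise
#'   an error naming the line.
#' @export
read_signal <- function(path) {
  if (!file.exists(path)) stopf("signal file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals)) {
    stopf("non-numeric signal value at line %d of %s",
          which(is.na(vals))[1], path)
  }
  vals
}

#' @rdname read_signal
#' @export
write_signal <- function(signal, path) {
  writeLines(format(signal, digits = 12, trim = TRUE, scientific = FALSE),
             path)
  invisible(path)
}

#' Read and write truth alignment tables
#'
#' Three-column TSV: `read_id`, `kmer_index` (1-based), `duration`.
#'
#' @param path file path.
#' @param reads list of [read_record()]s with truth.
#' @return `read_truth_table()` returns the data frame.
#' @export
write_truth_table <- function(reads, path) {
  df <- do.call(rbind, lapply(reads, function(r) {
    data.frame(read_id = r$read_id, kmer_index = r$truth_kmers,
               duration = r$truth_durations)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  if (!file.exists(path)) stopf("truth table not found: %s", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# Write a simulated run: per-read signal files, truth FASTA, truth TSV.
write_run <- function(reads, outdir, alphabet) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seqs <- vapply(reads, function(r)
    sequence_from_kmers(r$truth_kmers, alphabet), character(1))
  names(seqs) <- vapply(reads, `[[`, character(1), "read_id")
  write_fasta(seqs, file.path(outdir, "truth.fasta"))
  write_truth_table(reads, file.path(outdir, "truth_alignment.tsv"))
  for (r in reads) {
    write_signal(r$signal, file.path(outdir, paste0(r$read_id, ".signal.txt")))
  }
  invisible(outdir)
}

#' Read a simulated run back from disk
#'
#' Reconstructs the [read_record()] list written by
#' [simulate_run()]`(..., outdir = )`.
#'
#' @param outdir run directory.
#' @return list of [read_record()]s with truth.
#' @export
read_run <- function(outdir) {
  truth <- read_truth_table(file.path(outdir, "truth_alignment.tsv"))
  ids <- unique(truth$read_id)
  lapply(ids, function(id) {
    rows <- truth[truth$read_id == id, ]
    read_record(read_signal(file.path(outdir, paste0(id, ".signal.txt"))),
                read_id = id, truth_kmers = rows$kmer_index,
                truth_durations = rows$duration)
  })
}

#' Read and write a model configuration file
#'
#' YAML with fields `k`, `bases`, `transitions` (`mode`:
#' `uniform_shift` or `reference_counts` with `reference` sequence or file),
#' `dwell` (`a`, `b`, `Dbar`, `gamma` or `"mean-matched"`), `alpha`, and
#' either `emissions` (path to a [read_emission_table()] file, resolved
#' relative to the config) or `emissions_synthetic` (`spread`, `sigma`,
#' `seed` for [synthetic_level_table()]).
#'
#' @param path config file path.
#' @param model an [edhmm()] with a Gaussian observation.
#' @param emission_path where `write_model_config()` writes the emission
#'   table (default next to the config).
#' @return `read_model_config()` returns an [edhmm()].
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  ab <- kmer_alphabet(cfg$k %||% stopf("config needs 'k'"),
                      bases = unlist(cfg$bases) %||% c("A", "C", "G", "T"))
  tmode <- cfg$transitions$mode %||% "uniform_shift"
  tr <- switch(tmode,
    uniform_shift = uniform_shift_transitions(ab),
    reference_counts = {
      refseq <- cfg$transitions$reference %||%
        stopf("reference_counts mode needs 'transitions: reference'")
      if (file.exists(file.path(dirname(path), refseq))) {
        refseq <- paste(read_fasta(file.path(dirname(path), refseq)),
                        collapse = "")
      }
      count_transitions_from_reference(
        refseq, ab, pseudocount = cfg$transitions$pseudocount %||% 1)
    },
    stopf("unknown transition mode '%s'", tmode))
  dw <- cfg$dwell %||% stopf("config needs a 'dwell' block")
  dm <- duration_model(dw$a, dw$b, dw$Dbar,
                       gamma = dw$gamma %||% "mean-matched")
  obs <- if (!is.null(cfg$emissions)) {
    p <- cfg$emissions
    if (!file.exists(p)) p <- file.path(dirname(path), cfg$emissions)
    read_emission_table(p, ab)
  } else if (!is.null(cfg$emissions_synthetic)) {
    es <- cfg$emissions_synthetic
    synthetic_level_table(ab, spread = es$spread %||% 2,
                          sigma = es$sigma %||% 0.08,
                          seed = es$seed %||% 1L)
  } else NULL
  edhmm(ab, tr, dm, observation = obs, alpha = cfg$alpha %||% 1)
}

#' @rdname read_model_config
#' @export
write_model_config <- function(model, path,
                               emission_path = paste0(path, ".emissions.tsv")) {
  cfg <- list(
    k = model$alphabet$k,
    bases = as.list(model$alphabet$bases),
    transitions = list(mode = model$transitions$mode),
    dwell = list(a = model$durations$a, b = model$durations$b,
                 Dbar = model$durations$Dbar,
                 gamma = if (model$durations$gamma_mode == "mean-matched")
                   "mean-matched" else model$durations$gamma),
    alpha = model$alpha
  )
  if (!is.null(model$observation)) {
    write_emission_table(model$observation, emission_path, model$alphabet)
    cfg$emissions <- basename(emission_path)
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}
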