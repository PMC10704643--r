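#' Observation scorer contract
#'
#' An observation scorer maps a signal of `N` current samples to an
#' `N x size` matrix of per-sample, per-k-mer log-scores `log(phi[n, K])`
#' (strictly positive scores in the linear domain). Any object with a
#' `score_matrix()` method satisfies the contract; scorers must be
#' deterministic given their parameters and the input. The package provides
#' a Gaussian table scorer ([gaussian_observation()]), which is also the
#' reduced trainable reference used by [pretrain_scorer()]; heavier neural
#' scorers can be plugged in through the same generic.
#'
#' @param scorer a scorer object.
#' @param signal numeric vector of current samples.
#' @param ... passed to methods.
#' @return numeric `N x size` matrix of log-scores, all finite for finite
#'   input.
#' @export
score_matrix <- function(scorer, signal, ...) UseMethod("score_matrix")

#' Per-k-mer Gaussian emission model
#'
#' The classical squiggle observation model: while k-mer `K` occupies the
#' pore, each current sample is Normal with k-mer specific mean `mu[K]` and
#' standard deviation `sigma[K]` (normalized signal units). Scores are the
#' Normal densities.
#'
#' @param mu numeric vector of per-k-mer means (length = alphabet size).
#' @param sigma per-k-mer standard deviations (> 0); a scalar is recycled.
#' @param alphabet optional [kmer_alphabet()] used for names and validation.
#' @return An object of class `c("gaussian_obs")` with fields `mu`, `sigma`.
#' @export
gaussian_observation <- function(mu, sigma, alphabet = NULL) {
  sigma <- rep_len(as.numeric(sigma), length(mu))
  if (any(!is.finite(mu)) || any(!is.finite(sigma)) || any(sigma <= 0)) {
    stopf("'mu' must be finite and 'sigma' finite and > 0")
  }
  if (!is.null(alphabet)) {
    if (length(mu) != alphabet$size) {
      stopf("length(mu) = %d does not match alphabet size %d",
            length(mu), alphabet$size)
    }
    names(mu) <- names(sigma) <- alphabet$kmers
  }
  structure(list(mu = as.numeric(mu), sigma = sigma), class = "gaussian_obs")
}

#' @export
score_matrix.gaussian_obs <- function(scorer, signal, ...) {
  if (any(!is.finite(signal))) stopf("signal contains non-finite samples")
  n <- length(signal)
  mu <- scorer$mu
  sg <- scorer$sigma
  # log Normal density, N x |K|
  z <- outer(signal, mu, `-`)
  sweep(-0.5 * sweep(z^2, 2L, sg^2, `/`), 2L,
        0.5 * log(2 * pi * sg^2), `-`)
}

#' Gaussian log-score matrix for a signal
#'
#' Convenience wrapper around [score_matrix()] for a [gaussian_observation()]:
#' `log phi[n, K] = -0.5 * log(2 pi sigma_K^2) - (x_n - mu_K)^2 / (2 sigma_K^2)`.
#'
#' @param signal numeric vector of current samples.
#' @param obs a [gaussian_observation()].
#' @return `N x size` matrix of log-scores.
#' @export
gaussian_scores <- function(signal, obs) {
  stopifnot(inherits(obs, "gaussian_obs"))
  score_matrix(obs, signal)
}

#' @export
print.gaussian_obs <- function(x, ...) {
  cat(sprintf("Gaussian observation model over %d k-mers (mean sigma %.3g)\n",
              length(x$mu), mean(x$sigma)))
  invisible(x)
}

#' Synthetic per-k-mer current level table
#'
#' Builds a deterministic, well-spread table of normalized current levels for
#' simulation studies: levels are equally spaced on `[-spread, spread]` and
#' assigned to k-mers by a seeded permutation, so neighbouring k-mers get
#' unrelated levels (as in a real pore model) and all levels are distinct.
#' This is a synthetic stand-in for a measured pore level table.
#'
#' @param alphabet a [kmer_alphabet()].
#' @param spread half-width of the level range in normalized signal units.
#' @param sigma common emission standard deviation (default 0.08).
#' @param seed integer seed for the level permutation (default 1).
#' @return a [gaussian_observation()].
#' @export
synthetic_level_table <- function(alphabet, spread = 2, sigma = 0.08,
                                  seed = 1L) {
  nK <- alphabet$size
  levels <- if (nK == 1L) 0 else seq(-spread, spread, length.out = nK)
  perm <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    sample.int(nK)
  })
  gaussian_observation(levels[perm], sigma, alphabet)
}

#' Read / write a Gaussian emission table
#'
#' Three-column delimited text: k-mer string, mean, standard deviation.
#'
#' @param path file path.
#' @param obs a [gaussian_observation()] with named `mu` (written in table
#'   order).
#' @param alphabet a [kmer_alphabet()]; rows are matched to it by k-mer
#'   string when reading.
#' @return `read_emission_table()` returns a [gaussian_observation()];
#'   `write_emission_table()` returns `path` invisibly.
#' @export
read_emission_table <- function(path, alphabet) {
  if (!file.exists(path)) stopf("emission table not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stopf("emission table needs columns kmer, mean, sd")
  i <- match(alphabet$kmers, df[[1L]])
  if (anyNA(i)) stopf("emission table is missing k-mer '%s'",
                      alphabet$kmers[which(is.na(i))[1]])
  gaussian_observation(df[[2L]][i], df[[3L]][i], alphabet)
}

#' @rdname read_emission_table
#' @export
write_emission_table <- function(obs, path, alphabet) {
  df <- data.frame(kmer = alphabet$kmers, mean = obs$mu, sd = obs$sigma)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
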