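# Exact inference on the EDHMM lattice. All recursions run in natural-log
# domain with log-sum-exp; a state is the pair (K, d) of k-mer and duration
# countdown, stored as an nK x Dbar matrix per time step.
#
# Termination convention (alpha = 1): the geometric read-length prior is
# dropped and a path is valid iff it occupies some (K, 1) at the final
# sample, i.e. the last k-mer completes exactly at the end of the read. For
# Dbar = 1 the single duration bucket also carries the geometric tail, so
# termination contributes the extra exit factor (1 - gamma). With alpha < 1
# the end-state factor (1 - alpha) is included instead of being dropped.

term_const <- function(ss) {
  (if (ss$Dbar == 1L) ss$log_1mg else 0) +
    (if (ss$alpha < 1) log1p(-ss$alpha) else 0)
}

# One within-k-mer advance of a log-mass matrix (nK or M rows, Dbar columns):
# d counts down deterministically; the top bucket self-loops with gamma.
advance_log <- function(f, D, lg, l1mg) {
  if (D == 1L) return(f + lg)
  adv <- matrix(-Inf, nrow(f), D)
  if (D > 2L) adv[, 1:(D - 2L)] <- f[, 2:(D - 1L)]
  adv[, D - 1L] <- f[, D] + l1mg
  adv[, D] <- f[, D] + lg
  adv
}

fwd_free_core <- function(logphi, ss, keep = FALSE) {
  N <- nrow(logphi)
  nK <- ss$nK
  D <- ss$Dbar
  f <- ss$log_init + logphi[1L, ]
  FF <- if (keep) array(NA_real_, c(nK, D, N)) else NULL
  if (keep) FF[, , 1L] <- f
  if (N > 1L) {
    eta_row <- matrix(ss$log_eta_entry, nK, D, byrow = TRUE)
    for (n in 2:N) {
      adv <- advance_log(f, D, ss$log_gamma, ss$log_1mg)
      x1 <- f[, 1L]
      if (D == 1L) x1 <- x1 + ss$log_1mg
      pm <- matrix(x1[ss$pred], nK, ss$nb) + ss$logxi_pred
      ent_base <- row_logsumexp(pm) + ss$log_alpha
      f <- logaddexp(adv, ent_base + eta_row) + logphi[n, ]
      if (keep) FF[, , n] <- f
    }
  }
  ll <- logsumexp(f[, 1L]) + term_const(ss)
  list(log_likelihood = ll, last = f, forward = FF)
}

bwd_free_core <- function(logphi, ss) {
  N <- nrow(logphi)
  nK <- ss$nK
  D <- ss$Dbar
  BB <- array(-Inf, c(nK, D, N))
  b <- matrix(-Inf, nK, D)
  b[, 1L] <- term_const(ss)
  BB[, , N] <- b
  if (N > 1L) {
    eta_row <- matrix(ss$log_eta_entry, nK, D, byrow = TRUE)
    for (n in (N - 1L):1L) {
      g <- b + logphi[n + 1L, ]
      h <- row_logsumexp(g + eta_row)
      entK <- row_logsumexp(matrix(h[ss$succ], nK, ss$nb) + ss$logxi_succ) +
        ss$log_alpha
      bnew <- matrix(-Inf, nK, D)
      if (D == 1L) {
        bnew[, 1L] <- logaddexp(ss$log_gamma + g[, 1L], ss$log_1mg + entK)
      } else {
        bnew[, 1L] <- entK
        if (D > 2L) bnew[, 2:(D - 1L)] <- g[, 1:(D - 2L)]
        bnew[, D] <- logaddexp(ss$log_gamma + g[, D], ss$log_1mg + g[, D - 1L])
      }
      b <- bnew
      BB[, , n] <- b
    }
  }
  BB
}

fwd_clamped_core <- function(logphi, kmers, ss, keep = FALSE) {
  N <- nrow(logphi)
  D <- ss$Dbar
  kmers <- as.integer(kmers)
  if (any(is.na(kmers)) || any(kmers < 1L | kmers > ss$nK)) {
    stopf("invalid k-mer index in clamped sequence")
  }
  M <- length(kmers)
  # log alpha * xi(K_m | K_{m-1}) for the m-th entry (m >= 2)
  tw <- c(-Inf, if (M > 1L)
    log(ss$transitions$xi[cbind(kmers[-M], kmers[-1L])]) + ss$log_alpha)
  f <- matrix(-Inf, M, D)
  f[1L, ] <- ss$log_alpha + ss$log_xi0[kmers[1L]] + ss$log_eta_entry +
    logphi[1L, kmers[1L]]
  FF <- if (keep) array(NA_real_, c(M, D, N)) else NULL
  if (keep) FF[, , 1L] <- f
  if (N > 1L) {
    eta_row <- matrix(ss$log_eta_entry, M, D, byrow = TRUE)
    for (n in 2:N) {
      adv <- advance_log(f, D, ss$log_gamma, ss$log_1mg)
      x1 <- f[, 1L]
      if (D == 1L) x1 <- x1 + ss$log_1mg
      ent_base <- c(-Inf, x1[-M] + tw[-1L])
      f <- logaddexp(adv, ent_base + eta_row) + logphi[n, kmers]
      if (keep) FF[, , n] <- f
    }
  }
  ll <- f[M, 1L] + term_const(ss)
  list(log_likelihood = ll, last = f, forward = FF)
}

bwd_clamped_core <- function(logphi, kmers, ss) {
  N <- nrow(logphi)
  D <- ss$Dbar
  kmers <- as.integer(kmers)
  M <- length(kmers)
  tw <- c(-Inf, if (M > 1L)
    log(ss$transitions$xi[cbind(kmers[-M], kmers[-1L])]) + ss$log_alpha)
  BB <- array(-Inf, c(M, D, N))
  b <- matrix(-Inf, M, D)
  b[M, 1L] <- term_const(ss)
  BB[, , N] <- b
  if (N > 1L) {
    eta_row <- matrix(ss$log_eta_entry, M, D, byrow = TRUE)
    for (n in (N - 1L):1L) {
      g <- b + logphi[n + 1L, kmers]
      h <- row_logsumexp(g + eta_row)
      entm <- c(if (M > 1L) h[-1L] + tw[-1L], -Inf)
      bnew <- matrix(-Inf, M, D)
      if (D == 1L) {
        bnew[, 1L] <- logaddexp(ss$log_gamma + g[, 1L], ss$log_1mg + entm)
      } else {
        bnew[, 1L] <- entm
        if (D > 2L) bnew[, 2:(D - 1L)] <- g[, 1:(D - 2L)]
        bnew[, D] <- logaddexp(ss$log_gamma + g[, D], ss$log_1mg + g[, D - 1L])
      }
      b <- bnew
      BB[, , n] <- b
    }
  }
  BB
}

#' Free-running forward pass: data log-likelihood log p(X)
#'
#' Sums the probability of all k-mer/duration paths that explain the whole
#' signal (the free-running lattice), in log domain with log-sum-exp.
#'
#' @param scores `N x size` matrix of per-sample log-scores (see
#'   [score_matrix()]).
#' @param x an [edhmm()] model or [build_state_space()] result.
#' @param keep_forward keep the full `size x Dbar x N` log-forward array.
#' @return list of class `edhmm_trellis` with `log_likelihood` (`log p(X)`),
#'   `mode = "free_running"` and optionally `log_forward`.
#' @export
forward_free <- function(scores, x, keep_forward = FALSE) {
  ss <- as_state_space(x)
  check_scores(scores, ss)
  r <- fwd_free_core(scores, ss, keep = keep_forward)
  structure(list(log_likelihood = r$log_likelihood, mode = "free_running",
                 log_forward = r$forward),
            class = "edhmm_trellis")
}

#' Clamped forward pass: joint log-likelihood log p(K, X)
#'
#' Restricts the lattice to one k-mer sequence `K` (size `M x Dbar` per
#' sample) and sums over all duration assignments with total `N`. Returns
#' `-Inf` when no assignment fits (e.g. `M > N`).
#'
#' @inheritParams forward_free
#' @param kmers integer vector of k-mer indices (the clamped sequence `K`).
#' @return list of class `edhmm_trellis` with `log_likelihood`
#'   (`log p(K, X)`) and `mode = "clamped"`.
#' @export
forward_clamped <- function(scores, kmers, x, keep_forward = FALSE) {
  ss <- as_state_space(x)
  check_scores(scores, ss)
  r <- fwd_clamped_core(scores, kmers, ss, keep = keep_forward)
  structure(list(log_likelihood = r$log_likelihood, mode = "clamped",
                 log_forward = r$forward),
            class = "edhmm_trellis")
}

#' @export
print.edhmm_trellis <- function(x, ...) {
  cat(sprintf("EDHMM %s trellis: log-likelihood = %.6f\n",
              x$mode, x$log_likelihood))
  invisible(x)
}

#' Posterior k-mer occupancy per sample
#'
#' Forward-backward posterior probability that sample `n` was emitted by
#' k-mer `K`: `p(K_n = K | X)` on the free-running lattice, or
#' `p(K_n = K | X, K)` on the clamped lattice (mapped back to k-mer
#' identities) when `kmers` is given. Rows sum to 1.
#'
#' @inheritParams forward_clamped
#' @param kmers optional clamped k-mer sequence.
#' @return `N x size` matrix of posterior probabilities.
#' @export
occupancy <- function(scores, x, kmers = NULL) {
  ss <- as_state_space(x)
  check_scores(scores, ss)
  N <- nrow(scores)
  if (is.null(kmers)) {
    fw <- fwd_free_core(scores, ss, keep = TRUE)
    if (!is.finite(fw$log_likelihood)) stopf("zero-likelihood read")
    bw <- bwd_free_core(scores, ss)
    occ <- matrix(0, N, ss$nK)
    for (n in seq_len(N)) {
      occ[n, ] <- exp(row_logsumexp(matrix(fw$forward[, , n] + bw[, , n],
                                           ss$nK, ss$Dbar)) -
                        fw$log_likelihood)
    }
    colnames(occ) <- ss$alphabet$kmers
    return(occ)
  }
  kmers <- as.integer(kmers)
  fw <- fwd_clamped_core(scores, kmers, ss, keep = TRUE)
  if (!is.finite(fw$log_likelihood)) stopf("zero-likelihood read")
  bw <- bwd_clamped_core(scores, kmers, ss)
  M <- length(kmers)
  occm <- matrix(0, N, M)
  for (n in seq_len(N)) {
    occm[n, ] <- exp(row_logsumexp(matrix(fw$forward[, , n] + bw[, , n],
                                          M, ss$Dbar)) - fw$log_likelihood)
  }
  occ <- matrix(0, N, ss$nK)
  for (K in unique(kmers)) {
    occ[, K] <- rowSums(occm[, kmers == K, drop = FALSE])
  }
  colnames(occ) <- ss$alphabet$kmers
  occ
}

#' Jointly most likely k-mer and dwell sequence (Viterbi)
#'
#' Maximizes `p(K, D, X)` over all paths on the free-running lattice and
#' backtracks the maximizing pair. Ties are broken deterministically
#' (within-k-mer continuation preferred, then lowest predecessor k-mer
#' index). Dwell times include tail visits beyond `Dbar`.
#'
#' @inheritParams forward_free
#' @return list of class `edhmm_viterbi`: `kmers` (integer sequence `K`),
#'   `durations` (integer sequence `D`, `sum(durations) == N`), `log_joint`
#'   (`log p(K, D, X)`) and `labels` (per-sample k-mer index).
#' @export
viterbi_joint <- function(scores, x) {
  ss <- as_state_space(x)
  check_scores(scores, ss)
  N <- nrow(scores)
  nK <- ss$nK
  D <- ss$Dbar
  f <- ss$log_init + scores[1L, ]
  bp <- vector("list", N) # 0 = within-k-mer move, >0 = entry predecessor k-mer
  if (N > 1L) {
    eta_row <- matrix(ss$log_eta_entry, nK, D, byrow = TRUE)
    for (n in 2:N) {
      adv <- advance_log(f, D, ss$log_gamma, ss$log_1mg)
      x1 <- f[, 1L]
      if (D == 1L) x1 <- x1 + ss$log_1mg
      pm <- matrix(x1[ss$pred], nK, ss$nb) + ss$logxi_pred
      best <- pm[, 1L]
      if (ss$nb > 1L) for (j in 2:ss$nb) best <- pmax(best, pm[, j])
      argb <- max.col(pm, ties.method = "first")
      predk <- ss$pred[cbind(seq_len(nK), argb)]
      ent <- (best + ss$log_alpha) + eta_row
      take <- ent > adv # prefer continuation on exact ties
      f <- pmax(adv, ent) + scores[n, ]
      bpn <- matrix(0L, nK, D)
      bpn[take] <- matrix(predk, nK, D)[take]
      bp[[n]] <- bpn
    }
  }
  K <- which.max(f[, 1L])
  if (!is.finite(f[K, 1L])) stopf("no path has positive probability")
  log_joint <- f[K, 1L] + term_const(ss)
  labels <- integer(N)
  entry_at <- logical(N)
  d <- 1L
  labels[N] <- K
  entry_at[1L] <- TRUE
  if (N > 1L) {
    for (n in N:2L) {
      e <- bp[[n]][K, d]
      if (e > 0L) {
        entry_at[n] <- TRUE
        K <- e
        d <- 1L
      } else {
        d <- if (D == 1L) 1L else if (d <= D - 2L) d + 1L else D
      }
      labels[n - 1L] <- K
    }
  }
  bnd <- which(entry_at)
  durations <- diff(c(bnd, N + 1L))
  structure(list(kmers = labels[bnd], durations = as.integer(durations),
                 log_joint = log_joint, labels = labels),
            class = "edhmm_viterbi")
}

#' @export
print.edhmm_viterbi <- function(x, ...) {
  cat(sprintf("EDHMM Viterbi path: %d k-mers over %d samples, log joint = %.4f\n",
              length(x$kmers), sum(x$durations), x$log_joint))
  invisible(x)
}

#' Forced sample-to-k-mer alignment (clamped Viterbi)
#'
#' Finds the most likely duration assignment for a known k-mer sequence,
#' yielding per-sample k-mer labels (exactly `M` contiguous runs in the order
#' of `kmers`) and the dwell-time sequence. Used to build cross-entropy
#' pre-training labels.
#'
#' @inheritParams forward_clamped
#' @return list with `labels` (per-sample k-mer index, length `N`),
#'   `durations` (length `M`, summing to `N`) and `log_joint`.
#' @export
forced_alignment <- function(scores, kmers, x) {
  ss <- as_state_space(x)
  check_scores(scores, ss)
  kmers <- as.integer(kmers)
  if (any(is.na(kmers)) || any(kmers < 1L | kmers > ss$nK)) {
    stopf("invalid k-mer index in clamped sequence")
  }
  N <- nrow(scores)
  M <- length(kmers)
  if (M > N) stopf("alignment infeasible: %d k-mers but only %d samples", M, N)
  D <- ss$Dbar
  tw <- c(-Inf, if (M > 1L)
    log(ss$transitions$xi[cbind(kmers[-M], kmers[-1L])]) + ss$log_alpha)
  f <- matrix(-Inf, M, D)
  f[1L, ] <- ss$log_alpha + ss$log_xi0[kmers[1L]] + ss$log_eta_entry +
    scores[1L, kmers[1L]]
  bp <- vector("list", N) # TRUE = entry from previous k-mer
  if (N > 1L) {
    eta_row <- matrix(ss$log_eta_entry, M, D, byrow = TRUE)
    for (n in 2:N) {
      adv <- advance_log(f, D, ss$log_gamma, ss$log_1mg)
      x1 <- f[, 1L]
      if (D == 1L) x1 <- x1 + ss$log_1mg
      ent_base <- c(-Inf, x1[-M] + tw[-1L])
      ent <- ent_base + eta_row
      take <- ent > adv
      f <- pmax(adv, ent) + scores[n, kmers]
      bp[[n]] <- take
    }
  }
  if (!is.finite(f[M, 1L])) stopf("alignment infeasible for this read")
  log_joint <- f[M, 1L] + term_const(ss)
  m <- M
  d <- 1L
  midx <- integer(N)
  midx[N] <- m
  if (N > 1L) {
    for (n in N:2L) {
      if (bp[[n]][m, d]) {
        m <- m - 1L
        d <- 1L
      } else {
        d <- if (D == 1L) 1L else if (d <= D - 2L) d + 1L else D
      }
      midx[n - 1L] <- m
    }
  }
  durations <- as.integer(tabulate(midx, nbins = M))
  list(labels = kmers[midx], durations = durations, log_joint = log_joint)
}

#' Posterior probability of a k-mer sequence
#'
#' `p(K | X) = p(K, X) / p(X)`, computed as the ratio of the clamped and
#' free-running forward passes.
#'
#' @inheritParams forward_clamped
#' @return a probability in `[0, 1]`.
#' @export
sequence_posterior <- function(scores, kmers, x) {
  ss <- as_state_space(x)
  lpx <- fwd_free_core(scores, ss)$log_likelihood
  if (!is.finite(lpx)) stopf("data likelihood is zero")
  lpkx <- fwd_clamped_core(scores, kmers, ss)$log_likelihood
  exp(lpkx - lpx)
}

#' Exhaustive enumeration oracle for tiny instances
#'
#' Enumerates every k-mer sequence on the transition support together with
#' every duration composition of `N`, and accumulates exact path
#' probabilities by direct multiplication (tail durations handled
#' analytically up to `N`). Used as the independent reference for the
#' lattice algorithms; refuses instances with more than `max_paths` paths.
#'
#' @inheritParams forward_free
#' @param max_paths guard on the total number of `(K, D)` paths.
#' @return list with `log_px`, `sequences` (list of k-mer index vectors),
#'   `log_pkx` (per-sequence joint log-probability), `map` (the exact argmax
#'   path: `kmers`, `durations`, `log_joint`) and `occupancy` (exact
#'   `N x size` posterior).
#' @export
enumerate_bruteforce <- function(scores, x, max_paths = 200000L) {
  ss <- as_state_space(x)
  check_scores(scores, ss)
  N <- nrow(scores)
  nK <- ss$nK
  la <- ss$log_alpha
  lend <- if (ss$alpha < 1) log1p(-ss$alpha) else 0
  # all shift-valid sequences of length 1..N
  succ_ok <- lapply(seq_len(nK), function(K) {
    s <- ss$succ[K, ]
    s[is.finite(ss$logxi_succ[K, ])]
  })
  sequences <- list()
  frontier <- lapply(seq_len(nK), function(K) K)
  total_paths <- 0
  comps_cache <- list()
  compositions <- function(n, m) {
    key <- paste(n, m)
    if (!is.null(comps_cache[[key]])) return(comps_cache[[key]])
    out <- if (m == 1L) list(n) else {
      res <- list()
      for (first in seq_len(n - m + 1L)) {
        for (rest in compositions(n - first, m - 1L)) {
          res[[length(res) + 1L]] <- c(first, rest)
        }
      }
      res
    }
    comps_cache[[key]] <<- out
    out
  }
  for (M in seq_len(N)) {
    if (M > 1L) {
      frontier <- unlist(lapply(frontier, function(s) {
        lapply(succ_ok[[s[length(s)]]], function(K2) c(s, K2))
      }), recursive = FALSE)
    }
    ncomp <- choose(N - 1L, M - 1L)
    total_paths <- total_paths + length(frontier) * ncomp
    if (total_paths > max_paths) {
      stopf("instance too large to enumerate (> %d paths)", max_paths)
    }
    sequences <- c(sequences, frontier)
  }
  log_eta_tail <- log(duration_pmf(ss$durations, seq_len(N)))
  seq_ll <- numeric(length(sequences))
  occ_lin <- matrix(0, N, nK)
  best <- list(log_joint = -Inf, kmers = NULL, durations = NULL)
  for (si in seq_along(sequences)) {
    kseq <- sequences[[si]]
    M <- length(kseq)
    base <- la * M + lend + ss$log_xi0[kseq[1L]] +
      (if (M > 1L) sum(log(ss$transitions$xi[cbind(kseq[-M], kseq[-1L])])) else 0)
    lw <- -Inf
    for (comp in compositions(N, M)) {
      ends <- cumsum(comp)
      starts <- ends - comp + 1L
      lphi <- 0
      for (m in seq_len(M)) {
        lphi <- lphi + sum(scores[starts[m]:ends[m], kseq[m]])
      }
      lp <- base + sum(log_eta_tail[comp]) + lphi
      lw <- logaddexp(lw, lp)
      if (lp > best$log_joint) {
        best <- list(log_joint = lp, kmers = kseq, durations = comp)
      }
      if (is.finite(lp)) {
        w <- exp(lp)
        for (m in seq_len(M)) {
          occ_lin[starts[m]:ends[m], kseq[m]] <-
            occ_lin[starts[m]:ends[m], kseq[m]] + w
        }
      }
    }
    seq_ll[si] <- lw
  }
  log_px <- logsumexp(seq_ll)
  occ <- occ_lin / exp(log_px)
  list(log_px = log_px, sequences = sequences, log_pkx = seq_ll,
       map = best, occupancy = occ)
}
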