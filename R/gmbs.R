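# Greedy marginalized beam search (GMBS): approximate argmax_K p(K | X) by
# keeping a fixed-size list of k-mer prefixes ("beams"), each carrying its
# duration-resolved probability mass p(K_m, d | X_1..n) so duration can be
# marginalized exactly within a beam. Prefixes are stored in a backtrackable
# tree (parent pointer + appended k-mer per node).

new_beam_tree <- function(nb, capacity = 1024L) {
  tr <- new.env(parent = emptyenv())
  tr$parent <- integer(capacity)
  tr$label <- integer(capacity)
  tr$childmat <- matrix(0L, capacity, nb)
  tr$n <- 1L
  tr$parent[1L] <- 0L
  tr$label[1L] <- 0L # root: empty prefix
  class(tr) <- "beam_tree"
  tr
}

tree_grow <- function(tr, need) {
  cap <- length(tr$parent)
  if (need <= cap) return(invisible(tr))
  newcap <- max(2L * cap, need)
  tr$parent <- c(tr$parent, integer(newcap - cap))
  tr$label <- c(tr$label, integer(newcap - cap))
  cm <- matrix(0L, newcap, ncol(tr$childmat))
  cm[seq_len(cap), ] <- tr$childmat
  tr$childmat <- cm
  invisible(tr)
}

tree_add_nodes <- function(tr, parents, labels, register_b = NULL) {
  k <- length(parents)
  if (k == 0L) return(integer(0))
  tree_grow(tr, tr$n + k)
  ids <- tr$n + seq_len(k)
  tr$parent[ids] <- parents
  tr$label[ids] <- labels
  tr$n <- tr$n + k
  if (!is.null(register_b)) {
    tr$childmat[cbind(parents, register_b)] <- ids
  }
  ids
}

#' @export
print.beam_tree <- function(x, ...) {
  cat(sprintf("beam tree: %d nodes\n", x$n))
  invisible(x)
}

#' Read a beam-tree path back from a leaf to the root
#'
#' @param tree a beam tree as returned in `gmbs_decode(..., return_tree =
#'   TRUE)`.
#' @param leaf node id.
#' @return integer vector of k-mer labels on the root-to-leaf path (empty for
#'   the root itself).
#' @export
backtrack_tree <- function(tree, leaf) {
  if (!inherits(tree, "beam_tree")) stopf("'tree' is not a beam tree")
  leaf <- as.integer(leaf)
  if (is.na(leaf) || leaf < 1L || leaf > tree$n) stopf("dangling node reference")
  out <- integer(0)
  node <- leaf
  while (node != 1L) {
    out <- c(tree$label[node], out)
    node <- tree$parent[node]
    if (is.na(node) || node < 1L) stopf("dangling node reference")
  }
  out
}

#' Keep the top-B beams by total mass
#'
#' Stable pruning: beams are ranked by total duration-marginal mass in
#' decreasing order and ties keep their original (creation) order.
#'
#' @param beams list of beams, each a list with at least `duration_mass`
#'   (nonnegative numeric vector over duration states).
#' @param B maximum number of beams to keep.
#' @return the pruned beam list.
#' @export
prune_beams <- function(beams, B) {
  B <- as.integer(B)
  if (B < 1L) stopf("'B' must be >= 1")
  if (length(beams) <= B) return(beams)
  tot <- vapply(beams, function(b) sum(b$duration_mass), numeric(1))
  ord <- order(-tot, seq_along(tot)) # stable on ties
  beams[sort(ord[seq_len(B)])]
}

#' Decode a signal with greedy marginalized beam search
#'
#' Approximates the maximum-posterior k-mer sequence `argmax_K p(K | X)`.
#' At each sample every beam advances its duration mass through the
#' within-k-mer dynamics (deterministic countdown; the top bucket self-loops
#' with the tail factor `gamma`), beams with mass in the completion state
#' `d = 1` spawn an extension for every legal successor k-mer (entry mass
#' spread over entry durations by the duration model), beams that reach an
#' identical prefix are merged by summing their duration-mass vectors, and
#' the list is pruned to the best `beams` prefixes by total mass. Masses are
#' renormalized each step (the accumulated log constant is tracked), which
#' leaves the ranking unchanged. The answer is read out of the prefix tree
#' from the best completed leaf.
#'
#' @inheritParams forward_free
#' @param beams beam list size `B` (default 512).
#' @param return_tree also return the prefix tree and winning leaf id.
#' @return list of class `gmbs_result`: `kmers` (decoded k-mer index
#'   sequence), `sequence` (the base string), `log_mass` (log of the decoded
#'   prefix's accumulated joint mass, an estimate of `log p(K, X)` from the
#'   surviving paths), `n_nodes` (tree size), and optionally `tree`/`leaf`.
#' @export
gmbs_decode <- function(scores, x, beams = 512L, return_tree = FALSE) {
  ss <- as_state_space(x)
  check_scores(scores, ss)
  B <- as.integer(beams)
  if (B < 1L) stopf("'beams' must be >= 1")
  N <- nrow(scores)
  nK <- ss$nK
  D <- ss$Dbar
  nb <- ss$nb
  gamma <- ss$durations$gamma
  alpha_lin <- ss$alpha
  eta_lin <- ss$durations$eta_entry
  exit_fac <- if (D == 1L) (1 - gamma) else 1
  xiw <- exp(ss$logxi_succ) # nK x nb successor weights
  tr <- new_beam_tree(nb, capacity = max(1024L, 2L * B))

  # first sample: candidate beams are all k-mers entered from the start state
  m0 <- ss$log_init + scores[1L, ] # nK x D
  tot0 <- row_logsumexp(m0)
  keep0 <- which(is.finite(tot0))
  if (length(keep0) == 0L) stopf("decode failure: all beams have zero mass")
  ord0 <- keep0[order(-tot0[keep0])]
  sel0 <- ord0[seq_len(min(B, length(ord0)))]
  Cacc <- max(m0[sel0, ])
  mass <- exp(matrix(m0[sel0, ], length(sel0), D) - Cacc)
  labels <- sel0
  nodes <- tree_add_nodes(tr, rep(1L, length(sel0)), sel0)

  if (N > 1L) {
    for (n in 2:N) {
      lp <- scores[n, ]
      mx <- max(lp)
      if (!is.finite(mx)) stopf("decode failure: all beams have zero mass")
      pl <- exp(lp - mx)
      Cacc <- Cacc + mx
      Bn <- length(nodes)
      # within-k-mer advance
      if (D == 1L) {
        adv <- mass * gamma
      } else {
        adv <- matrix(0, Bn, D)
        if (D > 2L) adv[, 1:(D - 2L)] <- mass[, 2:(D - 1L)]
        adv[, D - 1L] <- mass[, D] * (1 - gamma)
        adv[, D] <- mass[, D] * gamma
      }
      adv <- adv * pl[labels]
      # extensions out of the completion state
      exitm <- mass[, 1L] * exit_fac * alpha_lin
      childk <- matrix(ss$succ[labels, ], Bn, nb)
      w <- exitm * matrix(xiw[labels, ], Bn, nb) *
        matrix(pl[childk], Bn, nb)
      childmass <- as.vector(w) %o% eta_lin # (Bn*nb) x D
      # candidate identity keys: a prefix is (parent node, appended base);
      # beams whose parent is the root get a reserved negative key
      par <- tr$parent[nodes]
      lastb <- (labels - 1L) %% nb + 1L
      advkey <- ifelse(par == 1L, -nodes, par * (nb + 1) + lastb)
      childkey <- as.vector(outer(nodes * (nb + 1), seq_len(nb), `+`))
      allkey <- c(advkey, childkey)
      allmass <- rbind(adv, childmass)
      tot <- rowSums(allmass)
      keep <- tot > 0
      if (!any(keep)) stopf("decode failure: all beams have zero mass")
      merged <- rowsum(allmass[keep, , drop = FALSE], group = allkey[keep])
      ukey <- as.numeric(rownames(merged))
      tot <- rowSums(merged)
      sel <- order(-tot)[seq_len(min(B, length(tot)))]
      mass <- merged[sel, , drop = FALSE]
      ukey <- ukey[sel]
      # resolve node ids, creating nodes only for surviving new prefixes
      nodes <- integer(length(ukey))
      neg <- ukey < 0
      nodes[neg] <- as.integer(-ukey[neg])
      if (any(!neg)) {
        pn <- as.integer(ukey[!neg] %/% (nb + 1))
        bb <- as.integer(ukey[!neg] %% (nb + 1))
        have <- tr$childmat[cbind(pn, bb)]
        miss <- have == 0L
        if (any(miss)) {
          newlab <- ss$succ[cbind(tr$label[pn[miss]], bb[miss])]
          have[miss] <- tree_add_nodes(tr, pn[miss], newlab,
                                       register_b = bb[miss])
        }
        nodes[!neg] <- have
      }
      labels <- tr$label[nodes]
      s <- max(tot[sel])
      mass <- mass / s
      Cacc <- Cacc + log(s)
    }
  }
  # completed-prefix score: the last k-mer must finish on the last sample
  final <- mass[, 1L] * exit_fac
  if (all(final == 0)) final <- rowSums(mass)
  best <- which.max(final)
  kmers <- backtrack_tree(tr, nodes[best])
  res <- list(
    kmers = kmers,
    sequence = sequence_from_kmers(kmers, ss$alphabet),
    log_mass = as.numeric(log(final[best])) + Cacc +
      (if (ss$alpha < 1) log1p(-ss$alpha) else 0),
    n_nodes = tr$n
  )
  if (return_tree) {
    res$tree <- tr
    res$leaf <- nodes[best]
  }
  structure(res, class = "gmbs_result")
}

#' @export
print.gmbs_result <- function(x, ...) {
  cat(sprintf("GMBS decode: %d k-mers (%d bases), log mass = %.4f, %d tree nodes\n",
              length(x$kmers), nchar(x$sequence), x$log_mass, x$n_nodes))
  invisible(x)
}
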