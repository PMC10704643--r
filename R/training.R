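# Conditional-maximum-likelihood training support. All gradients are taken
# with respect to the per-sample log-scores log phi[n, K]; by the standard
# lattice identity these are the posterior k-mer visit probabilities
# (occupancies), which is what makes hybrid HMM/network training practical:
#   d log p(X)    / d log phi[n, K] = p(K_n = K | X)
#   d log p(K, X) / d log phi[n, K] = p(K_n = K | X, K).

#' Gradients of the lattice log-likelihoods with respect to log-scores
#'
#' Free-running mode (default) returns `d log p(X) / d log phi`, which equals
#' the free-running occupancy; with a clamped sequence `kmers` it returns
#' `d log p(K, X) / d log phi`, the clamped occupancy mapped to k-mer
#' identities. Both are verified against central finite differences in the
#' test suite.
#'
#' @inheritParams forward_clamped
#' @param kmers optional clamped k-mer sequence.
#' @return list of class `edhmm_gradient`: `gradient` (`N x size` matrix),
#'   `loss` (the corresponding log-likelihood).
#' @export
score_gradients <- function(scores, x, kmers = NULL) {
  ss <- as_state_space(x)
  check_scores(scores, ss)
  if (is.null(kmers)) {
    ll <- fwd_free_core(scores, ss)$log_likelihood
  } else {
    ll <- fwd_clamped_core(scores, kmers, ss)$log_likelihood
  }
  if (!is.finite(ll)) stopf("zero-likelihood read; gradient undefined")
  g <- occupancy(scores, ss, kmers = kmers)
  structure(list(gradient = g, loss = ll), class = "edhmm_gradient")
}

#' Modified conditional-maximum-likelihood objective and gradient
#'
#' The plain CML objective `log p(K|X) = log p(K,X) - log p(X)` tends to be
#' maximized by driving `log p(X)` down, hurting generalization. The
#' modified objective regularizes with weight `lambda` in `[0, 1]`:
#'
#' * `variant = "free_running"`: `log p(K,X) - (1-lambda) log p(X)`;
#' * `variant = "beam"`: `log p(K,X) - (1-lambda) log p(K_BS, X)`, where
#'   `K_BS` is the current beam-search decode of the read and both terms are
#'   evaluated on clamped lattices, focusing the training signal on reads
#'   where the decoder disagrees with the reference.
#'
#' The objective is to be maximized; the returned gradient (with respect to
#' log-scores) is the matching combination of occupancies. If the beam decode
#' fails the beam variant falls back to the free-running form with a warning.
#'
#' @inheritParams forward_clamped
#' @param kmers the reference k-mer sequence `K` (feasible on the support).
#' @param lambda regularization weight in `[0, 1]`, default `1/2`.
#' @param variant `"free_running"` or `"beam"`.
#' @param beams beam list size for the beam variant.
#' @return list of class `edhmm_gradient` with `loss`, `gradient`, and for
#'   the beam variant `kmers_bs` (the decoded competitor sequence).
#' @export
modified_cml_loss <- function(scores, kmers, x, lambda = 0.5,
                              variant = c("free_running", "beam"),
                              beams = 64L) {
  variant <- match.arg(variant)
  if (lambda < 0 || lambda > 1) stopf("'lambda' must lie in [0, 1]")
  ss <- as_state_space(x)
  check_scores(scores, ss)
  ref <- score_gradients(scores, ss, kmers = kmers)
  kbs <- NULL
  if (variant == "beam") {
    dec <- tryCatch(gmbs_decode(scores, ss, beams = beams),
                    error = function(e) NULL)
    if (is.null(dec)) {
      warning("beam decode failed; falling back to free-running variant",
              call. = FALSE)
      variant <- "free_running"
    } else {
      kbs <- dec$kmers
    }
  }
  if (variant == "beam") {
    comp <- score_gradients(scores, ss, kmers = kbs)
  } else {
    comp <- score_gradients(scores, ss)
  }
  structure(list(
    loss = ref$loss - (1 - lambda) * comp$loss,
    gradient = ref$gradient - (1 - lambda) * comp$gradient,
    variant = variant, lambda = lambda, kmers_bs = kbs
  ), class = "edhmm_gradient")
}

#' Fit Gaussian emissions by Baum-Welch EM on clamped lattices
#'
#' Expectation-maximization for the per-k-mer Gaussian observation model,
#' with reads clamped to their reference k-mer sequences: the E-step computes
#' clamped occupancies (posterior sample-to-k-mer weights), the M-step
#' updates each k-mer's mean and variance by weighted moments. The total
#' clamped log-likelihood is non-decreasing across iterations. This is the
#' alignment model used to bootstrap sample-level labels before scorer
#' pre-training.
#'
#' @param reads list of [read_record()]s; each must carry `truth_kmers` (its
#'   reference k-mer sequence).
#' @param x an [edhmm()] whose `observation` is a [gaussian_observation()]
#'   used as the EM initialization.
#' @param max_iter maximum EM iterations.
#' @param tol stop when the relative log-likelihood improvement drops below
#'   this.
#' @param sigma_floor lower bound on fitted standard deviations (signal
#'   units) to prevent degenerate variances.
#' @return list of class `edhmm_em`: `model` (the input model with updated
#'   observation), `observation`, `loglik_trace` (per-iteration total
#'   clamped log-likelihood, evaluated after each M-step), and `visited`
#'   (logical: which k-mers had posterior mass; unvisited k-mers keep their
#'   initial parameters).
#' @export
fit_gaussian_em <- function(reads, x, max_iter = 25L, tol = 1e-6,
                            sigma_floor = 1e-3) {
  stopifnot(inherits(x, "edhmm"), inherits(x$observation, "gaussian_obs"))
  if (!length(reads)) stopf("no reads supplied")
  for (r in reads) {
    if (is.null(r$truth_kmers)) stopf("every read needs a reference k-mer sequence")
  }
  obs <- x$observation
  ss <- x$ss
  nK <- ss$nK
  trace <- numeric(0)
  prev <- -Inf
  for (it in seq_len(max_iter)) {
    s0 <- numeric(nK)
    s1 <- numeric(nK)
    s2 <- numeric(nK)
    ll <- 0
    for (r in reads) {
      lp <- score_matrix(obs, r$signal)
      fw <- fwd_clamped_core(lp, r$truth_kmers, ss)
      if (!is.finite(fw$log_likelihood)) {
        stopf("read %s has zero clamped likelihood under the current model",
              r$read_id %||% "?")
      }
      ll <- ll + fw$log_likelihood
      w <- occupancy(lp, ss, kmers = r$truth_kmers) # N x nK
      s0 <- s0 + colSums(w)
      s1 <- s1 + colSums(w * r$signal)
      s2 <- s2 + colSums(w * r$signal^2)
    }
    visited <- s0 > 1e-12
    mu <- obs$mu
    sg <- obs$sigma
    mu[visited] <- s1[visited] / s0[visited]
    v <- s2[visited] / s0[visited] - mu[visited]^2
    sg[visited] <- pmax(sqrt(pmax(v, 0)), sigma_floor)
    obs <- gaussian_observation(mu, sg, x$alphabet)
    # evaluate the updated model so the trace is the post-update likelihood
    ll_new <- 0
    for (r in reads) {
      lp <- score_matrix(obs, r$signal)
      ll_new <- ll_new + fwd_clamped_core(lp, r$truth_kmers, ss)$log_likelihood
    }
    trace <- c(trace, ll_new)
    if (is.finite(prev) && abs(ll_new - prev) <= tol * abs(prev)) break
    prev <- ll_new
  }
  model <- x
  model$observation <- obs
  structure(list(model = model, observation = obs, loglik_trace = trace,
                 visited = visited),
            class = "edhmm_em")
}

#' @export
print.edhmm_em <- function(x, ...) {
  cat(sprintf("EDHMM Gaussian EM fit: %d iterations, final log-lik %.4f\n",
              length(x$loglik_trace), x$loglik_trace[length(x$loglik_trace)]))
  invisible(x)
}

#' Pre-train an observation scorer on sample-level k-mer labels
#'
#' Minimizes the mean per-sample cross-entropy between the scorer's
#' softmax-normalized log-scores and one-hot k-mer labels (as produced by
#' [forced_alignment()]), by full-batch gradient descent with backtracking
#' line search (the step is halved until the loss does not increase, so the
#' loss trace is non-increasing). This initializes the scorer before the
#' heavier lattice-based CML training.
#'
#' @param data list of labelled reads: each element a list with `signal`
#'   (numeric vector) and `labels` (integer k-mer index per sample, same
#'   length).
#' @param scorer a trainable [gaussian_observation()] (means and log-sigmas
#'   are updated).
#' @param epochs number of gradient steps.
#' @param lr initial learning rate.
#' @param sigma_floor lower bound on sigmas.
#' @return list of class `edhmm_pretrain`: `scorer` (updated), `loss_trace`
#'   (cross-entropy per epoch, non-increasing), `accuracy` (final per-sample
#'   argmax accuracy on the training data).
#' @export
pretrain_scorer <- function(data, scorer, epochs = 30L, lr = 0.5,
                            sigma_floor = 1e-3) {
  stopifnot(inherits(scorer, "gaussian_obs"))
  xs <- unlist(lapply(data, function(d) {
    if (length(d$signal) != length(d$labels)) {
      stopf("label/signal length mismatch in pre-training data")
    }
    d$signal
  }))
  ys <- unlist(lapply(data, `[[`, "labels"))
  nK <- length(scorer$mu)
  if (any(ys < 1L | ys > nK)) stopf("label out of range")
  n <- length(xs)
  ce_loss <- function(mu, lsg) {
    lp <- score_matrix(gaussian_observation(mu, exp(lsg)), xs)
    lse <- row_logsumexp(lp)
    post <- exp(lp - lse)
    list(loss = -mean(lp[cbind(seq_len(n), ys)] - lse), post = post, lp = lp)
  }
  mu <- scorer$mu
  lsg <- log(scorer$sigma)
  cur <- ce_loss(mu, lsg)
  trace <- cur$loss
  step <- lr
  for (ep in seq_len(epochs)) {
    resid <- cur$post
    resid[cbind(seq_len(n), ys)] <- resid[cbind(seq_len(n), ys)] - 1
    # d CE / d mu_K and d CE / d log sigma_K through the Gaussian log-density
    z <- outer(xs, mu, `-`)
    sg2 <- exp(2 * lsg)
    gmu <- colSums(resid * sweep(z, 2L, sg2, `/`)) / n
    glsg <- colSums(resid * (sweep(z^2, 2L, sg2, `/`) - 1)) / n
    improved <- FALSE
    for (half in 0:20) {
      mu_try <- mu - step * gmu
      lsg_try <- pmax(lsg - step * glsg, log(sigma_floor))
      nxt <- ce_loss(mu_try, lsg_try)
      if (nxt$loss <= cur$loss + 1e-12) {
        mu <- mu_try
        lsg <- lsg_try
        cur <- nxt
        improved <- TRUE
        step <- step * 1.2
        break
      }
      step <- step / 2
    }
    trace <- c(trace, cur$loss)
    if (!improved) break
  }
  pred <- max.col(cur$lp, ties.method = "first")
  structure(list(
    scorer = gaussian_observation(mu, exp(lsg)),
    loss_trace = trace,
    accuracy = mean(pred == ys)
  ), class = "edhmm_pretrain")
}

#' @export
print.edhmm_pretrain <- function(x, ...) {
  cat(sprintf("scorer pre-training: %d epochs, CE %.4f -> %.4f, accuracy %.3f\n",
              length(x$loss_trace) - 1L, x$loss_trace[1],
              x$loss_trace[length(x$loss_trace)], x$accuracy))
  invisible(x)
}
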