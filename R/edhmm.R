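#' Explicit-duration HMM over k-mer states
#'
#' Constructs the generative model used throughout the package. A read is
#' generated by drawing a k-mer chain `K_1, ..., K_M` (first-order Markov,
#' one base per step), an independent dwell time `D_m` per k-mer from the
#' duration model, and `D_m` current samples per k-mer from the observation
#' model, so the signal length is `N = sum(D)`. The read-length prior is
#' geometric with continuation probability `alpha`; for inference `alpha = 1`
#' is the standard convention (the geometric prior factors are dropped and
#' termination is imposed by requiring the lattice path to complete its last
#' dwell on the final sample).
#'
#' @param alphabet a [kmer_alphabet()].
#' @param transitions a `kmer_transitions` object; default
#'   [uniform_shift_transitions()].
#' @param durations a [duration_model()].
#' @param observation an observation scorer (see [score_matrix()]), e.g. a
#'   [gaussian_observation()]; may be `NULL` if score matrices are supplied
#'   directly to the inference functions.
#' @param alpha read-continuation probability in `[0, 1]`; default 1.
#' @return An object of class `edhmm` with components `alphabet`,
#'   `transitions`, `durations`, `observation`, `alpha` and the derived
#'   state space `ss` (see [build_state_space()]).
#' @seealso [forward_free()], [viterbi_joint()], [gmbs_decode()],
#'   [simulate.edhmm()], [predict.edhmm()], [fit_gaussian_em()]
#' @examples
#' ab <- kmer_alphabet(1, c("A", "C", "G", "T"))
#' m <- edhmm(ab, durations = duration_model(3, 2.5, Dbar = 4),
#'            observation = synthetic_level_table(ab))
#' m
#' @export
edhmm <- function(alphabet, transitions = uniform_shift_transitions(alphabet),
                  durations, observation = NULL, alpha = 1) {
  stopifnot(inherits(alphabet, "kmer_alphabet"),
            inherits(transitions, "kmer_transitions"),
            inherits(durations, "duration_model"))
  if (alpha < 0 || alpha > 1) stopf("'alpha' must lie in [0, 1]")
  ss <- build_state_space(alphabet, transitions, durations, alpha)
  structure(list(alphabet = alphabet, transitions = transitions,
                 durations = durations, observation = observation,
                 alpha = alpha, ss = ss),
            class = "edhmm")
}

#' @export
print.edhmm <- function(x, ...) {
  cat("Explicit-duration HMM\n")
  print(x$alphabet)
  print(x$transitions)
  print(x$durations)
  if (!is.null(x$observation)) print(x$observation)
  cat(sprintf("alpha = %g; %d lattice states (plus start/end)\n",
              x$alpha, x$ss$nK * x$ss$Dbar))
  invisible(x)
}

#' @export
summary.edhmm <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
logLik.edhmm <- function(object, signal, ...) {
  lp <- model_scores(object, signal)
  ll <- forward_free(lp, object)$log_likelihood
  structure(ll, class = "logLik", df = NA_integer_, nobs = length(signal))
}

# Score matrix from the model's own observation scorer.
model_scores <- function(model, signal) {
  if (is.null(model$observation)) {
    stopf("model has no observation scorer; supply a score matrix directly")
  }
  score_matrix(model$observation, signal)
}

#' Build the EDHMM state space
#'
#' Expands the model into its lattice transition structure over states
#' `{A, B} union {(K, d)}` with `K` a k-mer and `d = 1..Dbar` a duration
#' countdown. Transition rules: the start state `A` enters `(K, d)` with
#' probability `alpha * xi0(K) * eta(d)` for `d < Dbar` and
#' `alpha * xi0(K) * eta(Dbar) / (1 - gamma)` for `d = Dbar` (the top bucket
#' absorbs the geometric tail), and goes to the end state `B` with `1 -
#' alpha`; `(K, d)` counts down deterministically to `(K, d - 1)` for
#' `2 <= d < Dbar`; `(K, Dbar)` self-loops with probability `gamma` and
#' moves to `(K, Dbar - 1)` with `1 - gamma`; `(K, 1)` enters a new k-mer
#' `(K', d')` with probability `alpha * xi(K'|K) * eta(d')` (top bucket again
#' tail-scaled) or ends the read with `1 - alpha`. A visit to `(K, 1)` marks
#' the completion of one k-mer.
#'
#' @param alphabet a [kmer_alphabet()].
#' @param transitions a `kmer_transitions`.
#' @param durations a [duration_model()].
#' @param alpha read-continuation probability.
#' @return An object of class `edhmm_statespace` holding the log transition
#'   tables consumed by the lattice algorithms, including `log_init` (the
#'   `size x Dbar` matrix of log entry probabilities from `A`) and
#'   `n_states = size * Dbar + 2`.
#' @export
build_state_space <- function(alphabet, transitions, durations, alpha = 1) {
  nK <- alphabet$size
  Dbar <- durations$Dbar
  sh <- shift_successors(alphabet)
  xi <- transitions$xi
  # gathered log transition weights on the shift support
  logxi_succ <- matrix(log(xi[cbind(rep(seq_len(nK), alphabet$nbases),
                                    as.vector(sh$succ))]),
                       nK, alphabet$nbases)
  logxi_pred <- matrix(log(xi[cbind(as.vector(sh$pred),
                                    rep(seq_len(nK), alphabet$nbases))]),
                       nK, alphabet$nbases)
  log_eta_entry <- log(durations$eta_entry)
  log_init <- log(alpha) + outer(log(transitions$xi0), log_eta_entry, `+`)
  structure(
    list(alphabet = alphabet, transitions = transitions,
         durations = durations, alpha = alpha,
         nK = nK, Dbar = Dbar, nb = alphabet$nbases,
         succ = sh$succ, pred = sh$pred,
         logxi_succ = logxi_succ, logxi_pred = logxi_pred,
         log_xi0 = log(transitions$xi0),
         log_eta_entry = log_eta_entry,
         log_gamma = log(durations$gamma),
         log_1mg = log1p(-durations$gamma),
         log_alpha = log(alpha),
         log_init = log_init,
         n_states = as.integer(nK * Dbar + 2L)),
    class = "edhmm_statespace"
  )
}

#' @export
print.edhmm_statespace <- function(x, ...) {
  cat(sprintf(
    "EDHMM state space: %d k-mers x Dbar = %d -> %d states (incl. start/end)\n",
    x$nK, x$Dbar, x$n_states))
  cat(sprintf("  %d k-mer transitions on the shift support; gamma = %.4f\n",
              sum(is.finite(x$logxi_succ)), x$durations$gamma))
  invisible(x)
}

# Accept either an edhmm model or a prebuilt state space everywhere.
as_state_space <- function(x) {
  if (inherits(x, "edhmm_statespace")) return(x)
  if (inherits(x, "edhmm")) return(x$ss)
  stopf("expected an 'edhmm' model or 'edhmm_statespace'")
}

check_scores <- function(logphi, ss) {
  if (!is.matrix(logphi) || nrow(logphi) < 1L) {
    stopf("'scores' must be an N x %d matrix of log-scores with N >= 1", ss$nK)
  }
  if (ncol(logphi) != ss$nK) {
    stopf("'scores' has %d columns; alphabet has %d k-mers",
          ncol(logphi), ss$nK)
  }
  if (any(is.na(logphi)) || any(logphi == Inf)) {
    stopf("'scores' must be finite log-scores (or -Inf for zero score)")
  }
  invisible(logphi)
}
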