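# Shared fixtures, all built in code.

tiny_alphabet <- function(k = 1L, nb = 2L) {
  kmer_alphabet(k, bases = c("A", "C", "G", "T")[seq_len(nb)])
}

# A small random EDHMM instance plus a random log-score matrix. Sizes are
# kept inside the enumeration guard so the brute-force oracle applies.
random_instance <- function(seed, nb = 2L, k = 1L, Dbar = 2L, N = 5L,
                            alpha = 1) {
  set.seed(seed)
  ab <- tiny_alphabet(k, nb)
  dm <- duration_model(a = runif(1, 1, 4), b = runif(1, 1.5, 3),
                       Dbar = Dbar, gamma = runif(1, 0, 0.6))
  model <- edhmm(ab, durations = dm, alpha = alpha)
  logphi <- matrix(rnorm(N * ab$size), N, ab$size)
  list(model = model, logphi = logphi, alphabet = ab)
}

# Enumerable instance mix used by the oracle-equivalence checks: bases in
# {2, 4}, k in {1, 2}, Dbar <= 3, N <= 7, sized to stay enumerable.
oracle_instances <- function(n = 20L) {
  lapply(seq_len(n), function(i) {
    set.seed(1000L + i)
    nb <- sample(c(2L, 4L), 1L)
    k <- if (nb == 2L) sample(1:2, 1L) else 1L
    N <- if (nb == 4L) sample(3:6, 1L) else sample(3:7, 1L)
    random_instance(seed = 2000L + i, nb = nb, k = k,
                    Dbar = sample(1:3, 1L), N = N,
                    alpha = sample(c(1, 0.9), 1L))
  })
}

# Reference model for simulation studies: k = 2, log-logistic dwell with
# mean ~6.6 samples, well-spread synthetic pore levels.
sim_model_k2 <- function(sigma = 0.12) {
  ab <- kmer_alphabet(2)
  edhmm(ab, durations = duration_model(5, 2.5, 8),
        observation = synthetic_level_table(ab, spread = 2, sigma = sigma))
}

sim_model_k3 <- function(sigma = 0.33, exclude_self = FALSE) {
  ab <- kmer_alphabet(3)
  edhmm(ab, uniform_shift_transitions(ab, exclude_self = exclude_self),
        durations = duration_model(5, 2.5, 8),
        observation = synthetic_level_table(ab, spread = 2, sigma = sigma))
}

# Central finite-difference check of a loss/gradient pair against the
# analytic gradient; returns the maximum relative error.
fd_max_rel_err <- function(fun, logphi, eps = 1e-4, floor = 1e-6) {
  an <- fun(logphi)
  g <- an$gradient
  maxrel <- 0
  for (n in seq_len(nrow(logphi))) {
    for (K in seq_len(ncol(logphi))) {
      up <- logphi; up[n, K] <- up[n, K] + eps
      dn <- logphi; dn[n, K] <- dn[n, K] - eps
      fd <- (fun(up)$loss - fun(dn)$loss) / (2 * eps)
      maxrel <- max(maxrel, abs(fd - g[n, K]) / max(abs(g[n, K]), floor))
    }
  }
  maxrel
}
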