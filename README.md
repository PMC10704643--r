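# edcall

Explicit-duration hidden Markov model (EDHMM) basecalling for nanopore
signals, at desk scale.

## The problem

A nanopore sequencer reports a noisy ion-current trace (a "squiggle"); at
any instant the current level is dominated by the k-mer occupying the pore,
and the number of consecutive samples per k-mer (the *dwell time*) is random
because the ratcheting enzyme advances the strand irregularly. Basecalling
must therefore jointly segment the trace and identify the k-mer path. Plain
HMMs force dwell times to be geometric, which is wrong for real enzymes and
hurts most in homopolymers, where the current is flat and dwell statistics
are the only signal.

`edcall` implements the computational core of a hybrid EDHMM basecaller for
this setting:

* **Model.** A read is generated as
  `p(X, K, D) = zeta(M) * [xi0(K1) prod xi(Km|Km-1)] * [prod eta(Dm)] *
  [prod prod phi(X(m,d)|Km)]`:
  a first-order k-mer chain `K` advancing one base per step, independent
  dwell times `D` from a discretized log-logistic `eta` with a geometric
  tail (factor `gamma` beyond the maximum explicit duration `Dbar`), and
  per-sample emission scores `phi` (Gaussian tables, or any pluggable
  scorer via the `score_matrix()` generic). The state space is
  `{A, B} + |K| x Dbar` duration-countdown states.
* **Inference.** Exact forward/backward, posterior occupancy, Viterbi and
  forced alignment on both the *clamped* lattice (one fixed sequence `K`,
  giving `p(K, X)`) and the *free-running* lattice (all sequences, giving
  `p(X)`), all in log domain; plus an exhaustive enumeration oracle for
  small instances.
* **Decoding.** A greedy marginalized beam search (GMBS) that keeps `B`
  high-posterior k-mer prefixes, each carrying a duration-resolved mass
  vector so dwell time is marginalized exactly within a beam, stored in a
  backtrackable prefix tree. Long reads are decoded in 4096-sample chunks
  with 296-sample overlap and stitched.
* **Training.** Score-space gradients (`d log p / d log phi` = posterior
  occupancy), the modified conditional-maximum-likelihood objectives
  `log p(K,X) - (1-lambda) log p(X)` and
  `log p(K,X) - (1-lambda) log p(K_BS,X)`, Baum-Welch EM for Gaussian
  emissions, and cross-entropy pre-training of a scorer on forced-alignment
  labels.
* **Simulation and evaluation.** A squiggle simulator drawing exactly from
  the generative model (with optional per-read dwell drift emulating ATP
  depletion), Levenshtein identity metrics
  (`identity = matches / alignment columns`), and homopolymer accuracy.

## Worked example

```r
library(edcall)

ab  <- kmer_alphabet(3)                           # 64 k-mer states
mod <- edhmm(ab,
             durations   = duration_model(a = 5, b = 2.5, Dbar = 8),
             observation = synthetic_level_table(ab, spread = 2, sigma = 0.3))
mod
#> Explicit-duration HMM
#> k-mer alphabet: k = 3 over {A,C,G,T} (64 states)
#> k-mer transition model (uniform_shift): 64 x 64, 256 nonzero entries
#> dwell-time model: log-logistic(a = 5, b = 2.5) x 1, Dbar = 8, gamma = 0.8441 (mean-matched)
#>   mean dwell = 6.607 samples
#> Gaussian observation model over 64 k-mers (mean sigma 0.3)
#> alpha = 1; 512 lattice states (plus start/end)

read <- simulate_read(mod, seed = 42, length_mode = "fixed", M = 60)
read
#> read read_1: 366 samples, truth: 60 k-mers

call  <- predict(mod, list(read), beams = 64)
truth <- sequence_from_kmers(read$truth_kmers, ab)
align_and_score(call[[1]], truth)
#> alignment: identity 0.9839 (61 match / 0 mismatch / 0 ins / 1 del over 62 columns)
```

The identity is the fraction of matched alignment columns between the
decoded sequence and the simulated truth; here the decode drops a single
base (one deletion column). At heavier noise (sigma around 0.33,
where the median Viterbi identity drops to roughly 0.85 on 100-read
batches) the duration-marginalizing beam search recovers measurably better
sequences than the jointly-optimal Viterbi path (`decoder = "viterbi"`).

A command-line wrapper for `simulate`, `basecall`, `evaluate` and
`train-em` is installed under `inst/scripts/edcall`.

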