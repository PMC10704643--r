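---
title: "Explicit-duration HMM basecalling: model, algorithms and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explicit-duration HMM basecalling: model, algorithms and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edcall)
```

## The generative model

`edcall` models a raw nanopore read as the output of a hierarchical
generative process. A k-mer chain $K_1,\dots,K_M$ is drawn first-order
Markov: $K_1 \sim \xi_0$, $K_m \sim \xi(\cdot \mid K_{m-1})$, where the
support of $\xi$ is the single-base-shift relation (the last $k-1$ bases of
$K_{m-1}$ equal the first $k-1$ bases of $K_m$, one new base per step).
Each k-mer independently draws a dwell time $D_m \sim \eta$, the number of
current samples emitted while it occupies the pore, and each of those
samples is drawn from the emission model $\varphi(\cdot \mid K_m)$. The
joint density factorizes as

$$
p(X, K, D) \;=\; \zeta(M)\,
\xi_0(K_1)\prod_{m=2}^{M}\xi(K_m\mid K_{m-1})\;
\prod_{m=1}^{M}\eta(D_m)\;
\prod_{m=1}^{M}\prod_{d=1}^{D_m}\varphi(X_{(m,d)}\mid K_m),
$$

with $N = \sum_m D_m$ samples in total and a geometric read-length prior
$\zeta(M) = (1-\alpha)\alpha^{M}$.

The point of the *explicit* duration state is that $\eta$ need not be
geometric. Dwell times of real ratcheting enzymes are not memoryless, and
in homopolymer stretches the current is flat, so dwell statistics are the
only information about run length; a dedicated dwell distribution is where
that prior knowledge lives.

### Dwell-time distribution

`duration_model(a, b, Dbar, gamma)` discretizes a log-logistic
distribution with scale `a` (samples; the mean dwell is proportional to
`a`) and shape `b` by half-integer CDF differences,
$\eta(d) = F(d+\tfrac12) - F(d-\tfrac12)$ for $d < \bar D$. A continuous
dwell law has no canonical discretization; CDF differences were chosen
because they preserve total mass and are monotone in the density. Beyond the maximum explicit duration
$\bar D$ the distribution has a geometric tail,
$\eta(\bar D + m) = \gamma^m \eta(\bar D)$, realized in the state space as
a self-loop, and $\eta(\bar D)$ is fixed so the total mass is exactly one.
With `gamma = "mean-matched"` (the default) the tail factor is solved in
closed form so the discrete mean equals the continuous log-logistic mean
$a\,(\pi/b)/\sin(\pi/b)$ — the tail then carries a representative mean
dwell rather than being an arbitrary cut-off. The study models in the
tests use `a = 5, b = 2.5, Dbar = 8` (mean dwell 6.6 samples), a
realistic translocation speed for ~4 kHz sampling at ~450 bases/s.

Per-read dwell variation (reads sequenced later in a run dwell longer as
ATP depletes) is a single multiplicative knob on `a`:
`rescale_duration()`, with `estimate_duration_scale()` providing a direct
estimate of a read's mean dwell as $N$ divided by the number of
single-sample level changes exceeding `change_threshold` (default 0.1)
times the read's MAD, clipped to a configured range. The threshold is
deliberately below the minimum level gap of the synthetic tables (~0.27
normalized units) and far above the diff noise at high SNR; the estimate
degrades gracefully toward the clip bounds for constant or
jump-every-sample signals. Any smooth calibration against run features
could replace it; only the scale knob is load-bearing.

### State space

The model is encoded with start/end states $A,B$ and $|\mathbb K|\times
\bar D$ intermediate states $(K, d)$, where $d$ counts down the remaining
dwell: $A \to (K,d)$ with $\alpha\,\xi_0(K)\,\tilde\eta(d)$; $(K,d) \to
(K,d-1)$ deterministically for $2 \le d < \bar D$; $(K,\bar D)$ self-loops
with $\gamma$ and steps down with $1-\gamma$; $(K,1) \to (K',d')$ with
$\alpha\,\xi(K'\mid K)\,\tilde\eta(d')$ or exits to $B$ with $1-\alpha$.
Here $\tilde\eta$ is $\eta$ with the top bucket scaled by $(1-\gamma)^{-1}$
so it absorbs the whole tail. A visit to $(K,1)$ marks the completion of
one k-mer.

For inference $\alpha = 1$: the geometric length prior is dropped
(otherwise a length-$10^5$ read would need $\alpha$ absurdly close to 1
and the prior is ill-defined at exactly 1), and read termination is
imposed by conditioning instead — a path is valid iff it occupies some
$(K,1)$ at the last sample, i.e. the final dwell completes exactly at the
end of the read. Whether a real pore truncates mid-dwell at the end of a
read is not observable at this level; completing-on-the-last-sample is the
convention used throughout, consistently in the forward passes, Viterbi,
the beam search's final ranking, and the enumeration oracle (for
$\bar D = 1$, where the single bucket carries the tail, termination
contributes the extra exit factor $1-\gamma$). With $\alpha < 1$ the
$(1-\alpha)$ factors are kept instead, and all algorithms still agree with
enumeration — the tests exercise both.

## Exact inference

`forward_free()` computes $\log p(X)$ over all paths, `forward_clamped()`
computes $\log p(K, X)$ on the lattice restricted to one sequence (size
$M \times \bar D$ per sample), and their difference gives the sequence
posterior $p(K \mid X)$. `occupancy()` runs forward-backward for the
posterior visit probabilities $p(K_n = K \mid X)$ — rows sum to one —
and `viterbi_joint()`/`forced_alignment()` give the jointly most likely
$(K, D)$ on the free and clamped lattices. All recursions run in natural
log domain with log-sum-exp; no scaling vectors, so likelihoods far below
double range are handled uniformly. Viterbi ties are broken
deterministically (continuation preferred, then lowest predecessor index);
the oracle tests use continuous random scores so ties have measure zero.

Everything above is validated against `enumerate_bruteforce()`, an
independent oracle that explicitly enumerates every shift-valid sequence
and every duration composition of $N$ and multiplies path probabilities
directly. It is deliberately naive (and guarded by a path-count limit);
agreement to $10^{-9}$ relative on seeded instances over $\{2,4\}$ bases,
$k \le 2$, $\bar D \le 3$, $N \le 7$ is asserted in the tests.

## Decoding

The sequence with maximal posterior $p(K \mid X)$ is not the Viterbi
output: Viterbi maximizes over $(K, D)$ jointly, while the quantity of
interest marginalizes dwell. The greedy marginalized beam search
(`gmbs_decode()`) maintains up to $B$ k-mer prefixes; each beam carries a
mass vector over the dwell state $d$, so marginalization within a prefix
is exact. Per sample, each beam advances through the within-k-mer
dynamics, beams with mass at $d = 1$ spawn one extension per legal
successor (entry mass spread over entry durations by $\tilde\eta$), beams
reaching an identical prefix are merged by summing mass vectors, and the
list is pruned to the top $B$ by total mass. Prefixes live in a parent-
pointer tree (at most $NB + 1$ nodes; nodes are only created for
surviving beams) and the answer is read from the best completed leaf —
ranked by the mass in $d = 1$, matching the termination convention, so
that with $B$ large enough to avoid pruning the decode equals the exact
posterior argmax (asserted against enumeration). Per-step renormalization
keeps masses in linear-domain range; the accumulated constant is returned
with the winning mass, which then equals $\log p(K, X)$ exactly in the
no-pruning case.

The source the beam search derives from leaves its precise
extension/merge schedule open; the variant above (advance, extend at
$d=1$, merge, prune) satisfies every property stated for it — fixed-size
list, per-beam duration marginalization, tree storage, the node bound —
and those properties, not the schedule, are what the tests pin down.

On noisy reads the ordering expected of the two decoders holds: at the
study condition (k = 3, level table of spread 2, emission sigma 0.33 —
calibrated so the Viterbi-projected identity is near 0.85) the GMBS with
64 beams attains a higher median identity than the Viterbi projection over
a 100-read batch, and one beam is far worse than 64.

Long signals are decoded in overlapping chunks (`chunk_signal()`, default
4096 samples with 296 overlap) and reassembled by `stitch_sequences()`,
which ends-free-aligns the suffix of each chunk's call against the prefix
of the next and cuts at the junction, keeping overlap bases once. How the
original systems reconcile disagreements inside the overlap is not
documented; cutting at the best-scoring junction was chosen because it is
deterministic and exact for consistent calls (asserted), and on simulated
~12,000-sample reads it costs at most 0.01 identity versus whole-read
decoding (also asserted).

## Training

For hybrid training the useful fact is that the gradient of either lattice
log-likelihood with respect to the per-sample log-scores is an occupancy:
$\partial \log p(X) / \partial \log\varphi_{n,K} = p(K_n = K \mid X)$ and
likewise for the clamped lattice. The package states the gradients in log
domain (occupancy = gradient of the log-likelihood); a formulation of the
same relation written for raw probabilities would need an extra likelihood
factor, and the finite-difference tests (agreement to $10^{-5}$ relative,
typically $10^{-9}$) pin the log-domain form down as the correct one.

Plain conditional maximum likelihood, maximizing
$\log p(K \mid X) = \log p(K,X) - \log p(X)$, can be gamed by pushing
$\log p(X)$ down — the scorer stops modelling the data. The modified
objective keeps a $\lambda$-weighted share of the data likelihood:
$\log p(K,X) - (1-\lambda)\log p(X)$ with $\lambda = \tfrac12$ by default,
or, in the beam variant, $\log p(K,X) - (1-\lambda)\log p(K_{BS},X)$ with
$K_{BS}$ the current beam-search decode and both terms clamped — the
objective then concentrates on reads where the decoder disagrees with the
reference, and collapses to $\lambda \log p(K,X)$ when it doesn't.
`modified_cml_loss()` returns the objective and its occupancy-combination
gradient; a failed decode falls back to the free-running form with a
warning.

`fit_gaussian_em()` is Baum-Welch for the Gaussian emission table with
reads clamped to their references: E-step clamped occupancies, M-step
weighted means/variances with a sigma floor (default $10^{-3}$ signal
units) against degenerate variance; k-mers with no posterior mass keep
their initialization. The trace is the post-update likelihood, so EM
monotonicity is assertable and asserted. On 200 simulated reads (k = 2,
75 k-mers per read, about 500 samples) it recovers the true means to well
under 5% of the level range.

`pretrain_scorer()` is the reduced, pluggable counterpart of a neural
scorer: any object with a `score_matrix()` method can stand in, and the
provided trainable Gaussian table is fitted to forced-alignment labels by
full-batch gradient descent on the per-sample cross-entropy with a
backtracking line search, so the loss trace is non-increasing by
construction. The contract tested is loss decrease and label accuracy, not
a particular trajectory; a full residual-LSTM scorer is out of scope here
and would plug into the same generic.

## The simulator, and what passing tests do not show

`simulate_read()`/`simulate_run()` draw exactly from the generative model
above: geometric read length (truncated at $M \ge 1$; with continuation
0.99 the truncation biases the mean about 1% above $\alpha/(1-\alpha)$,
inside the 5% band checked), the shift-valid k-mer chain, dwell times from
the explicit head by inverse CDF plus a geometric tail, and Gaussian
samples per dwell step. Dwell drift across a run is modelled as
multiplicative growth $(1+\text{rate})^i$ in read index $i$ — the
phenomenon (ATP depletion) is real, its functional form here is a choice,
and the default rate is 0. Synthetic level tables
(`synthetic_level_table()`) place distinct, equally spaced levels assigned
to k-mers by a seeded permutation; real pore tables are neither equally
spaced nor composition-free, and real noise is neither white nor Gaussian
(no event stutter, no adapter artefacts, no normalization drift within a
read). Passing tests therefore demonstrate correctness of the algorithms
under the model's own assumptions, not basecalling accuracy on real
squiggles.

One identifiability point matters for the zero-noise exactness study: a
homopolymer k-mer may legally follow itself, and such a transition leaves
the current level unchanged, so the split of a flat run into equal-level
dwells is unidentifiable — the posterior argmax merges the dwells
($\eta(d_1+d_2) \gg \eta(d_1)\eta(d_2)\xi$) and exact truth recovery is
impossible in principle, not a decoder defect. The exactness study
therefore uses `uniform_shift_transitions(exclude_self = TRUE)`, under
which every transition moves the level; the noisy-decoder studies keep
self-shifts. This is the desk-scale face of the homopolymer
undercounting that plagues real basecallers, and it is why the dwell
model, not the level model, is the only handle on run length.

## Numerical and design notes

* Observation scores are shared across the dwell state ($\varphi$ depends
  on $K$ only), and all score matrices are log-domain `N x |K|`.
* k-mer indices are 1-based in R; the index/string bijection is big-endian
  positional in the declared base order and round-trips by construction.
* $\xi_0$ defaults to uniform; reference-count estimation
  (`count_transitions_from_reference()`) uses the empirical k-mer
  frequency for $\xi_0$, pseudocounts on the shift support only, and
  uniform fallback for unobserved rows.
* Study sizes in tests and the acceptance script (20 enumerable instances;
  200 EM reads of ~500 samples; 100 decoder reads of 60 k-mers; two
  ~12,000-sample chunked reads; $10^5$ dwell draws; $10^4$ length draws)
  were chosen to make each check statistically meaningful at interactive
  runtimes on one CPU.
* Known limitations: no quality scores on basecalls; no FAST5/POD5
  ingestion (signals are plain text); evaluation is against per-read
  simulator truth, not a reference genome; the duration-scale estimator is
  a heuristic stand-in for a calibrated regression; dense transition
  matrices cap practical alphabets around $k = 5$ (1024 states), matching
  the intended desk scale.
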