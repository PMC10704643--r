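Package: edcall
Title: Explicit-Duration Hidden Markov Model Basecalling for Nanopore Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling raw nanopore current traces with an explicit
    duration hidden Markov model (EDHMM) over k-mer states. Provides the model
    components (k-mer alphabets, single-base-shift transition models,
    log-logistic dwell-time distributions with a geometric tail, Gaussian and
    pluggable observation scorers), exact forward/backward, Viterbi and forced
    alignment on the semi-Markov lattice, a greedy marginalized beam-search
    decoder, conditional-maximum-likelihood training gradients and Baum-Welch
    fitting of Gaussian emissions, a synthetic squiggle simulator with ground
    truth, and alignment-based accuracy metrics including homopolymer scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
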