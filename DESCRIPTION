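Package: evoscape
Title: Protein Fitness Landscape Inference from Directed-Evolution Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers a Potts (pairwise) protein fitness landscape from
    multi-round directed-evolution sequencing data by modelling the
    experiment as a mutation-selection Markov chain over codon sequences.
    Provides error-prone-PCR-style codon mutation kernels, exact
    transition-kernel oracles on enumerable sequence spaces, a stochastic
    population simulator, approximate recursive moment propagation,
    moment-matching estimation of mean parameters with mean-field
    inversion to canonical Potts parameters, and landscape analysis tools:
    mutation-effect maps, zero-sum-gauge Frobenius interaction scores,
    contact positive predictive value, epistasis classification, and
    greedy adaptive walks. A synthetic-data generator with planted ground
    truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
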