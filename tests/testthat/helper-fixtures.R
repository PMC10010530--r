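# Shared fixtures and independent oracles for the test suite.
# Oracle implementations here are deliberately written as plain loops,
# separate from the package's vectorized code paths.

ALPHABET <- codon_alphabet()

# uniform nucleotide bias (all substitutions equally likely)
uniform_bias <- function() {
  m <- matrix(1, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  diag(m) <- 0
  m
}

# a dense random Potts model over all position pairs
random_dense_potts <- function(L, seed, field_sd = 1, coupling_sd = 1) {
  set.seed(seed)
  h <- matrix(rnorm(L * 20, 0, field_sd), L, 20)
  pairs <- all_pairs(L)
  blocks <- array(rnorm(400 * nrow(pairs), 0, coupling_sd),
                  c(20, 20, nrow(pairs)))
  potts_model(h, pairs, blocks)
}

# oracle: score a single amino-acid index vector by explicit summation
oracle_score <- function(model, aa) {
  s <- model$offset
  for (i in seq_along(aa)) s <- s + model$h[i, aa[i]]
  if (nrow(model$pairs) > 0) {
    for (p in seq_len(nrow(model$pairs))) {
      i <- model$pairs[p, 1]; j <- model$pairs[p, 2]
      s <- s + model$blocks[aa[i], aa[j], p]
    }
  }
  s
}

# oracle: classify one double mutant from its four genotype scores
oracle_epistasis_class <- function(s00, s10, s01, s11, tol = 1e-9) {
  sgn <- function(x) if (abs(x) < tol) 0L else as.integer(sign(x))
  dA <- s10 - s00; dB <- s01 - s00
  dAB <- s11 - s01; dBA <- s11 - s10
  flipA <- sgn(dA) != 0L && sgn(dAB) == -sgn(dA)
  flipB <- sgn(dB) != 0L && sgn(dBA) == -sgn(dB)
  if (flipA && flipB) "reciprocal_sign"
  else if (xor(flipA, flipB)) "sign"
  else "additive"
}

# small trajectory fixture shared by inference tests (neutral landscape)
tiny_trajectory <- function(L = 3, rounds = 3, seed = 7) {
  mm <- build_mutation_model(read_bias_tsv(), 0.5, L)
  wt <- c(5L, 20L, 40L)[seq_len(L)]
  ds <- simulate_trajectory(wt, mm, NULL, rounds = rounds, pop_size = 200,
                            brood = 10, sample_sizes = 100, seed = seed)
  freqs <- lapply(ds$rounds, empirical_frequencies)
  names(freqs) <- names(ds$rounds)
  list(mm = mm, wt = wt, ds = ds, freqs = freqs)
}
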