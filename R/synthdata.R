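# Synthetic fixtures with planted ground truth: sparse Potts landscapes
# whose coupled pairs double as a planted contact map, and simulated
# directed-evolution trajectories over them. Every pipeline stage is
# testable against these without any external data.

#' Generate a planted sparse Potts landscape
#'
#' Fields are i.i.d. zero-mean normal with the given scale; couplings are
#' zero except at `n_coupled_pairs` randomly chosen long-range pairs
#' (separation > 5), where 20 x 20 blocks are drawn normal and zero-sum
#' gauged. The wild type is the field-argmax sequence perturbed at
#' `n_perturb` random sites (so the experiment starts near, not on, the
#' additive optimum), encoded with random synonymous codons. The planted
#' contact map assigns the coupled pairs a distance of 4 Angstrom and all
#' other long-range pairs 10 Angstrom.
#'
#' @param L residues (default 30, the desk-scale profile).
#' @param n_coupled_pairs planted long-range coupled pairs (default 5).
#' @param field_scale sd of field parameters (default 0.3). Calibrated
#'   once, together with `coupling_scale`, so that the planted couplings
#'   leave a statistically visible covariation signal in samples of 2000
#'   sequences per round: weaker fields keep standing variation alive at
#'   the coupled sites, which is what makes couplings observable at all.
#' @param coupling_scale sd of coupling blocks before gauging
#'   (default 1.5).
#' @param n_perturb wild-type sites moved off the field argmax
#'   (default 3).
#' @param seed RNG seed.
#' @return object of class `planted_truth`: `landscape` ([potts_model]),
#'   `planted_pairs`, `wildtype` (codon indices), `contacts`
#'   (`contact_map`), `config`.
#' @export
generate_landscape <- function(L = 30L, n_coupled_pairs = 5L,
                               field_scale = 0.3, coupling_scale = 1.5,
                               n_perturb = 3L, seed = 1L) {
  set.seed(as.integer(seed))
  ab <- codon_alphabet()
  pairs_all <- all_pairs(L)
  long <- pairs_all[pairs_all[, 2] - pairs_all[, 1] > 5L, , drop = FALSE]
  stopifnot(n_coupled_pairs <= nrow(long))
  h <- matrix(stats::rnorm(L * 20L, 0, field_scale), L, 20L)
  sel <- sort(sample.int(nrow(long), n_coupled_pairs))
  planted <- long[sel, , drop = FALSE]
  # graded per-pair strengths so that recovering their relative order is a
  # well-posed question (equal strengths would be statistically tied)
  strengths <- coupling_scale *
    seq(0.7, 1.3, length.out = max(n_coupled_pairs, 1L))
  blocks <- array(stats::rnorm(400L * n_coupled_pairs, 0, 1),
                  c(20L, 20L, n_coupled_pairs))
  for (p in seq_len(n_coupled_pairs)) {
    blk <- blocks[, , p] * strengths[p]
    blocks[, , p] <- blk - outer(rowMeans(blk), rep(1, 20)) -
      outer(rep(1, 20), colMeans(blk)) + mean(blk)
  }
  landscape <- potts_model(h, planted, blocks)
  wt_aa <- max.col(h, ties.method = "first")
  if (n_perturb > 0L) {
    sites <- sample.int(L, n_perturb)
    for (s in sites)
      wt_aa[s] <- sample(setdiff(1:20, wt_aa[s]), 1L)
  }
  wt <- vapply(wt_aa, function(a) {
    cands <- which(ab$ac_map == a)
    cands[sample.int(length(cands), 1L)]
  }, integer(1))
  dist <- rep(10, nrow(long)); dist[sel] <- 4
  contacts <- contact_map(long[, 1], long[, 2], dist)
  structure(list(landscape = landscape, planted_pairs = planted,
                 planted_strengths = strengths[seq_len(n_coupled_pairs)],
                 wildtype = wt, contacts = contacts,
                 config = list(L = L, n_coupled_pairs = n_coupled_pairs,
                               field_scale = field_scale,
                               coupling_scale = coupling_scale,
                               n_perturb = n_perturb, seed = seed)),
            class = "planted_truth")
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf("planted_truth: L = %d, %d planted long-range coupled pair(s), seed %d\n",
              x$config$L, x$config$n_coupled_pairs, x$config$seed))
  invisible(x)
}

#' Simulate a trajectory dataset over a planted landscape
#'
#' Wraps the population simulator with the packaged default error-prone
#' PCR bias scaled to the target per-gene DNA mutation load, producing a
#' sampled multi-round dataset plus a manifest describing the run.
#'
#' @param truth a `planted_truth`.
#' @param rounds rounds of evolution (default 8).
#' @param pop_size population size (default 5000).
#' @param brood offspring per parent (default 100).
#' @param sample_sizes sequences sampled per sequenced round
#'   (default 2000).
#' @param sampled_rounds rounds to sequence (default all).
#' @param target_load expected DNA substitutions per gene per round
#'   (default 4).
#' @param bias 4x4 nucleotide bias (default the packaged synthetic table).
#' @param seed RNG seed.
#' @return object of class `synthetic_trajectory`: `dataset`
#'   ([trajectory_dataset]), `mutation_model`, `truth`, `manifest`.
#' @export
generate_trajectory_dataset <- function(truth, rounds = 8L, pop_size = 5000L,
                                        brood = 100L, sample_sizes = 2000L,
                                        sampled_rounds = seq_len(rounds),
                                        target_load = 4,
                                        bias = read_bias_tsv(),
                                        seed = 1L) {
  stopifnot(inherits(truth, "planted_truth"))
  L <- truth$config$L
  model <- build_mutation_model(bias, target_load, L)
  dataset <- simulate_trajectory(truth$wildtype, model, truth$landscape,
                                 rounds = rounds, pop_size = pop_size,
                                 brood = brood,
                                 sample_sizes = sample_sizes,
                                 sampled_rounds = sampled_rounds,
                                 seed = seed)
  stats <- population_stats(dataset)
  manifest <- list(generator = "evoscape synthetic trajectory",
                   truth_config = truth$config,
                   rounds = rounds, pop_size = pop_size, brood = brood,
                   sample_sizes = rep_len(sample_sizes,
                                          length(sampled_rounds)),
                   sampled_rounds = sampled_rounds,
                   target_load = target_load, seed = seed,
                   population_stats = stats)
  structure(list(dataset = dataset, mutation_model = model, truth = truth,
                 manifest = manifest),
            class = "synthetic_trajectory")
}

#' @export
print.synthetic_trajectory <- function(x, ...) {
  cat("synthetic_trajectory:\n")
  print(x$truth)
  print(x$dataset)
  invisible(x)
}

#' Write a synthetic trajectory to disk (FASTA + truth + manifest)
#' @param synth a `synthetic_trajectory`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_synthetic_trajectory <- function(synth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in synth$dataset$rounds)
    write_round_fasta(s, file.path(dir, sprintf("round_%02d.fasta", s$round)))
  wt <- Biostrings::DNAStringSet(codons_to_dna(synth$dataset$wildtype))
  names(wt) <- "wildtype"
  Biostrings::writeXStringSet(wt, file.path(dir, "wildtype.fasta"))
  write_potts(synth$truth$landscape, file.path(dir, "truth_landscape.json"))
  write_contact_map(synth$truth$contacts, file.path(dir, "contacts.tsv"))
  jsonlite::write_json(synth$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
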