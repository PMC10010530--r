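# Mutation-selection Markov chain: per-lineage transition law
#   p(x -> y) = g(x -> y) * pi(y) / sum_z g(x -> z) * pi(z)
# with pi proportional to exp(Potts score of the translated sequence).
# Exact kernels are available on enumerable spaces (the oracle used by the
# tests); the scalable path is a finite-brood stochastic population
# simulator whose per-parent law converges to the exact kernel as the
# brood size grows.

#' Enumerate a codon sequence space
#'
#' @param L residues.
#' @param codons codon indices allowed at every position (default all 61).
#' @return integer matrix (n_states x L), rows in odometer order with the
#'   last position varying fastest.
#' @export
enumerate_states <- function(L, codons = 1:61) {
  ns <- length(codons)^L
  if (ns > 2e7) stop("state space too large to enumerate (", ns, " states)",
                     call. = FALSE)
  g <- do.call(expand.grid, rev(replicate(L, codons, simplify = FALSE)))
  m <- as.matrix(g[, rev(seq_len(L)), drop = FALSE])
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

#' Exact mutation-selection transition kernel on an enumerated space
#'
#' Refuses spaces whose full transition matrix would exceed the
#' enumeration budget rather than truncating silently.
#'
#' @param model a `mutation_model`.
#' @param landscape a [potts_model] (or `NULL` for a flat landscape).
#' @param states integer state matrix from [enumerate_states].
#' @return object of class `transition_kernel`: list with `states` and
#'   `matrix` (row-stochastic n x n).
#' @export
exact_kernel <- function(model, landscape, states) {
  ns <- nrow(states)
  if (ns * ns > 2.5e7)
    stop("state space too large for an exact kernel (", ns, " states; ",
         ns * ns, " entries)", call. = FALSE)
  G <- matrix(1, ns, ns)
  for (i in seq_len(ncol(states))) {
    Ki <- kernel_for(model, i)
    G <- G * Ki[states[, i], states[, i], drop = FALSE]
  }
  if (is.null(landscape)) {
    pi_ <- rep(1, ns)
  } else {
    ab <- codon_alphabet()
    aa <- matrix(ab$ac_map[states], nrow = ns)
    sc <- score_sequences(landscape, aa)
    pi_ <- exp(sc - max(sc))
  }
  P <- G * matrix(pi_, ns, ns, byrow = TRUE)
  P <- P / rowSums(P)
  structure(list(states = states, matrix = P), class = "transition_kernel")
}

#' Propagate a state distribution through the exact kernel
#'
#' @param kernel a `transition_kernel`.
#' @param p0 probability vector over the kernel's states.
#' @param rounds number of transitions to apply.
#' @return matrix `(rounds + 1) x n_states`; row r+1 is the distribution
#'   after r rounds (row 1 is `p0`).
#' @export
propagate_exact <- function(kernel, p0, rounds) {
  stopifnot(length(p0) == nrow(kernel$matrix),
            abs(sum(p0) - 1) < 1e-8, all(p0 >= 0))
  out <- matrix(NA_real_, rounds + 1L, length(p0))
  out[1L, ] <- p0
  p <- p0
  for (r in seq_len(rounds)) {
    p <- as.vector(p %*% kernel$matrix)
    out[r + 1L, ] <- p
  }
  out
}

#' First-order codon marginals of enumerated-state distributions
#' @param states integer state matrix.
#' @param p probability vector (or matrix with distributions in rows).
#' @return L x 61 marginal matrix (or list of them).
#' @export
state_marginals <- function(states, p) {
  if (is.matrix(p)) return(lapply(seq_len(nrow(p)), function(r)
    state_marginals(states, p[r, ])))
  L <- ncol(states)
  m <- matrix(0, L, 61L)
  for (i in seq_len(L))
    m[i, ] <- vapply(1:61, function(c) sum(p[states[, i] == c]), numeric(1))
  m
}

# Stochastic population simulator -------------------------------------------

# sample codon targets for a column of parent codons under one kernel
.mutate_column <- function(parent, kernel) {
  out <- integer(length(parent))
  for (c in unique(parent)) {
    idx <- which(parent == c)
    out[idx] <- sample.int(61L, length(idx), replace = TRUE,
                           prob = kernel[c, ])
  }
  out
}

#' One round of finite-brood mutation-selection
#'
#' Each parent independently draws `brood` mutagenized offspring from the
#' codon kernels, and one offspring per parent survives with probability
#' proportional to its fitness exp(score). Competition is strictly within
#' a parent's brood (lineage-local selection); as the brood size grows the
#' per-parent transition law converges to the exact kernel.
#'
#' @param pop a [round_sample] (the current population).
#' @param model a `mutation_model`.
#' @param landscape a [potts_model] or `NULL` for neutral drift.
#' @param brood offspring per parent (B >= 1).
#' @return a [round_sample] for the next round, same population size.
#' @export
simulate_round <- function(pop, model, landscape, brood = 100L) {
  stopifnot(inherits(pop, "round_sample"), brood >= 1L)
  seqs <- pop$seqs
  N <- nrow(seqs); L <- ncol(seqs)
  B <- as.integer(brood)
  off <- matrix(0L, N * B, L)
  for (i in seq_len(L)) {
    par_col <- rep(seqs[, i], each = B)
    off[, i] <- .mutate_column(par_col, kernel_for(model, i))
  }
  if (is.null(landscape)) {
    pick <- sample.int(B, N, replace = TRUE)
  } else {
    ab <- codon_alphabet()
    aa <- matrix(ab$ac_map[off], nrow = N * B)
    sc <- matrix(score_sequences(landscape, aa), N, B, byrow = TRUE)
    # Gumbel-max: argmax of score + Gumbel noise samples the softmax exactly
    gum <- -log(-log(stats::runif(N * B)))
    pick <- max.col(sc + matrix(gum, N, B), ties.method = "first")
  }
  keep <- (seq_len(N) - 1L) * B + pick
  round_sample(off[keep, , drop = FALSE], pop$round + 1L)
}

#' Simulate a directed-evolution trajectory
#'
#' Initializes the population as N copies of the wild-type, applies
#' [simulate_round] `rounds` times, and samples (without replacement) the
#' requested number of sequences at each sampled round.
#'
#' @param wildtype integer codon-index vector or DNA string.
#' @param model a `mutation_model`.
#' @param landscape a [potts_model] or `NULL`.
#' @param rounds total rounds of evolution.
#' @param pop_size population size N (constant across rounds).
#' @param brood offspring per parent per round.
#' @param sample_sizes integer, one per sampled round (recycled).
#' @param sampled_rounds rounds at which to emit samples (default all).
#' @param seed integer seed; identical seed and configuration give a
#'   bit-identical dataset.
#' @return a [trajectory_dataset]; the final population is attached as
#'   attribute `"final_population"`.
#' @export
simulate_trajectory <- function(wildtype, model, landscape, rounds,
                                pop_size = 10000L, brood = 100L,
                                sample_sizes = 1000L,
                                sampled_rounds = seq_len(rounds),
                                seed = 1L) {
  if (is.character(wildtype)) wildtype <- dna_to_codons(wildtype)
  stopifnot(rounds >= 0L, pop_size >= 1L, all(sampled_rounds >= 1L),
            all(sampled_rounds <= max(rounds, 1L)))
  n0 <- as.integer(sample_sizes[1L])
  sample_sizes <- rep_len(as.integer(sample_sizes), length(sampled_rounds))
  if (any(c(n0, sample_sizes) > pop_size))
    stop("sample size exceeds population size", call. = FALSE)
  set.seed(as.integer(seed))
  pop <- round_sample(matrix(rep(as.integer(wildtype), each = pop_size),
                             nrow = pop_size), 0L)
  samples <- list()
  if (rounds == 0L) {
    samples[[1L]] <- round_sample(pop$seqs[seq_len(n0), , drop = FALSE], 0L)
  } else {
    for (r in seq_len(rounds)) {
      pop <- simulate_round(pop, model, landscape, brood)
      k <- match(r, sampled_rounds)
      if (!is.na(k)) {
        take <- sample.int(pop_size, sample_sizes[k])
        samples[[length(samples) + 1L]] <-
          round_sample(pop$seqs[take, , drop = FALSE], r)
      }
    }
  }
  out <- trajectory_dataset(wildtype, samples)
  attr(out, "final_population") <- pop
  out
}
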