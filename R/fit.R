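# Top-level modelling interface: fit_landscape() runs the whole inference
# pipeline (empirical frequencies -> moment matching -> mean-field
# inversion) and returns a classed fit with the usual accessor methods.

#' Fit a Potts fitness landscape to a directed-evolution trajectory
#'
#' The full inference pipeline: per-round empirical codon frequencies,
#' moment-matching estimation of the landscape's mean parameters under
#' the mutation-selection dynamics, and regularized mean-field inversion
#' to canonical Potts parameters (fields and couplings), anchored in the
#' wild-type reference gauge.
#'
#' @param data a [trajectory_dataset].
#' @param mutation_model a `mutation_model`; by default built from the
#'   packaged bias at 4 DNA substitutions per gene per round.
#' @param config an [inference_config].
#' @param verbose print optimization progress.
#' @return object of class `evoscape_fit`: the canonical `model`
#'   ([potts_model]), the `mean_fit` (gamma, marginals, loss trace), the
#'   `config`, the training `data` summary and the wild type.
#' @examples
#' \donttest{
#' truth <- generate_landscape(L = 10, n_coupled_pairs = 2, seed = 1)
#' synth <- generate_trajectory_dataset(truth, rounds = 4, pop_size = 500,
#'                                      brood = 25, sample_sizes = 300,
#'                                      seed = 1)
#' fit <- fit_landscape(synth$dataset, synth$mutation_model,
#'                      config = inference_config(max_steps = 50))
#' print(fit)
#' }
#' @export
fit_landscape <- function(data, mutation_model = NULL,
                          config = inference_config(), verbose = FALSE) {
  stopifnot(inherits(data, "trajectory_dataset"))
  L <- length(data$wildtype)
  if (is.null(mutation_model))
    mutation_model <- build_mutation_model(read_bias_tsv(), 4, L)
  mfit <- fit_mean_parameters(data, mutation_model, config = config,
                              verbose = verbose)
  wt_aa <- aa_of(data$wildtype)
  # reference state per site: the most probable amino acid under the
  # fitted marginals. Anchoring at a well-populated state keeps the
  # (q-1)-dimensional restriction well conditioned; the wild-type amino
  # acid can be nearly absent at swept sites. Score differences (and so
  # mutation-effect maps) are gauge-independent either way.
  model <- invert_to_canonical(mfit$marginals, config$lambda_reg)
  structure(list(model = model, mean_fit = mfit, config = config,
                 wildtype = data$wildtype, wildtype_aa = wt_aa,
                 mutation_model = mutation_model,
                 data_summary = population_stats(data),
                 rounds = data$sequenced_rounds,
                 call = match.call()),
            class = "evoscape_fit")
}

#' @export
print.evoscape_fit <- function(x, ...) {
  cat("Potts fitness landscape fitted to a directed-evolution trajectory\n")
  cat(sprintf("  L = %d residues; sequenced rounds: %s\n",
              x$model$L, paste(x$rounds, collapse = ", ")))
  cat(sprintf("  moment matching: %d steps, loss %.6g -> %.6g\n",
              x$mean_fit$steps, x$mean_fit$initial_loss,
              x$mean_fit$loss_trace[length(x$mean_fit$loss_trace)]))
  invisible(x)
}

#' @export
summary.evoscape_fit <- function(object, n_top = 10L, ...) {
  sc <- interaction_scores(object$model)
  top <- utils::head(top_interactions(sc), n_top)
  mem <- mutation_effect_map(object$model, object$wildtype_aa)
  best <- which(mem == max(mem), arr.ind = TRUE)[1, ]
  ab <- codon_alphabet()
  out <- list(L = object$model$L, rounds = object$rounds,
              data_summary = object$data_summary,
              top_interactions = top,
              best_single_mutation = sprintf(
                "%s%d%s (effect %.4g)",
                ab$amino_acids[object$wildtype_aa[best[1]]], best[1],
                ab$amino_acids[best[2]], max(mem)),
              final_loss = object$mean_fit$loss_trace[
                length(object$mean_fit$loss_trace)])
  class(out) <- "summary.evoscape_fit"
  out
}

#' @export
print.summary.evoscape_fit <- function(x, ...) {
  cat(sprintf("Fitted Potts landscape: L = %d, rounds %s\n", x$L,
              paste(x$rounds, collapse = ", ")))
  cat("\nPer-round population statistics:\n")
  print(x$data_summary, row.names = FALSE)
  cat("\nTop long-range interaction scores (Frobenius, zero-sum gauge):\n")
  print(x$top_interactions, row.names = FALSE)
  cat("\nLargest beneficial single mutation:", x$best_single_mutation, "\n")
  invisible(x)
}

#' @export
coef.evoscape_fit <- function(object, ...) {
  list(h = object$model$h, pairs = object$model$pairs,
       e = object$model$blocks)
}

#' Predict log-fitness scores for new sequences
#' @param object an `evoscape_fit`.
#' @param newdata amino-acid strings, an index matrix, or a
#'   [round_sample] (codon sequences are translated).
#' @param ... unused.
#' @return numeric vector of scores relative to the fitted gauge.
#' @export
predict.evoscape_fit <- function(object, newdata, ...) {
  if (inherits(newdata, "round_sample")) {
    ab <- codon_alphabet()
    newdata <- matrix(ab$ac_map[newdata$seqs], nrow = nrow(newdata$seqs))
  }
  score_sequences(object$model, newdata)
}

#' @export
logLik.evoscape_fit <- function(object, ...) {
  ll <- -object$mean_fit$loss_trace[length(object$mean_fit$loss_trace)]
  attr(ll, "df") <- length(object$mean_fit$gamma$first) +
    length(object$mean_fit$gamma$second)
  class(ll) <- "logLik"
  ll
}

#' Residuals: empirical minus predicted codon frequencies per round
#'
#' The fitted marginals are propagated through the moment recursion from
#' the wild-type delta; residuals are the differences to the observed
#' first-order frequencies at each sequenced round.
#'
#' @param object an `evoscape_fit`.
#' @param data the training [trajectory_dataset] (per-round samples are
#'   not stored in the fit).
#' @param ... unused.
#' @return named list (per round) of L x 61 residual matrices.
#' @export
residuals.evoscape_fit <- function(object, data, ...) {
  stopifnot(inherits(data, "trajectory_dataset"))
  marg <- object$mean_fit$marginals
  mu_land <- moment_vector(marg$mu_first)
  cur <- init_moments(object$wildtype, second = FALSE)
  out <- list()
  for (r in seq_len(max(data$sequenced_rounds))) {
    cur <- propagate_moments(mu_land, cur, object$mutation_model)
    k <- as.character(r)
    if (k %in% names(data$rounds)) {
      f <- empirical_frequencies(data$rounds[[k]], second = FALSE)
      out[[k]] <- f$first - cur$first
    }
  }
  out
}

#' Simulate new trajectories from a fitted landscape
#' @param object an `evoscape_fit`.
#' @param nsim number of trajectories.
#' @param seed RNG seed.
#' @param rounds,pop_size,brood,sample_sizes simulator settings (smaller
#'   defaults than the training data for quick checks).
#' @param ... unused.
#' @return list of [trajectory_dataset]s.
#' @export
simulate.evoscape_fit <- function(object, nsim = 1, seed = 1L, rounds = 5L,
                                  pop_size = 1000L, brood = 50L,
                                  sample_sizes = 500L, ...) {
  lapply(seq_len(nsim), function(k)
    simulate_trajectory(object$wildtype, object$mutation_model,
                        object$model, rounds = rounds,
                        pop_size = pop_size, brood = brood,
                        sample_sizes = sample_sizes,
                        seed = as.integer(seed) + k - 1L))
}

#' Plot a fitted landscape
#'
#' `type = "effects"` draws the single-mutant effect heatmap around the
#' wild type (wild-type entries are zero/white); `type = "loss"` the
#' optimization loss trace; `type = "interactions"` the Frobenius
#' interaction-score matrix.
#'
#' @param x an `evoscape_fit`.
#' @param type one of `"effects"`, `"loss"`, `"interactions"`.
#' @param ... passed to the underlying base-graphics call.
#' @export
plot.evoscape_fit <- function(x, type = c("effects", "loss", "interactions"),
                              ...) {
  type <- match.arg(type)
  ab <- codon_alphabet()
  if (type == "loss") {
    plot(seq_along(x$mean_fit$loss_trace) - 1L, x$mean_fit$loss_trace,
         type = "l", xlab = "step", ylab = "loss",
         main = "moment-matching loss", ...)
  } else if (type == "effects") {
    mem <- mutation_effect_map(x$model, x$wildtype_aa)
    lim <- max(abs(mem))
    graphics::image(seq_len(x$model$L), 1:20, mem, zlim = c(-lim, lim),
                    col = grDevices::hcl.colors(101, "Blue-Red 2"),
                    xlab = "position", ylab = "amino acid", axes = FALSE,
                    main = "single-mutant effects", ...)
    graphics::axis(1); graphics::axis(2, at = 1:20, labels = ab$amino_acids,
                                      las = 2, cex.axis = 0.6)
  } else {
    sc <- interaction_scores(x$model)
    graphics::image(seq_len(x$model$L), seq_len(x$model$L), sc$F,
                    col = grDevices::hcl.colors(101, "YlOrRd", rev = TRUE),
                    xlab = "position", ylab = "position",
                    main = "interaction scores (Frobenius)", ...)
  }
  invisible(x)
}
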