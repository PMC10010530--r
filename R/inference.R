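# Moment-matching estimation of the landscape's mean parameters.
#
# The landscape marginals mu are reparameterized at the amino-acid level
# through gamma (per-site and per-pair softmaxes), codon-level marginals
# assign equal mass to synonymous codons by construction, and the loss is
# the aggregated log-loss between empirical per-round codon frequencies
# and the frequencies predicted by chaining the wild-type delta
# initialization through the recursive moment propagation, plus l2
# regularizers on gamma and a quadratic local-consistency penalty.
# Gradients are analytic (reverse-mode, derived by hand) and checked
# against finite differences in the test suite. Canonical Potts
# parameters are recovered from the fitted marginals by regularized
# mean-field inversion of the connected-correlation matrix.

#' Inference configuration
#'
#' Defaults: Adam with learning rate 0.03, l2 strengths 1e-3 (main) and
#' 1e-2 (interactions), local-consistency multiplier 1e5, inversion
#' regularization 50, validation-based early stopping. Like ridge
#' strengths in direct coupling analysis, the interaction regularizer
#' must be scaled to the data: with hundreds of position pairs and a few
#' thousand sequences per round, weaker values (1e-4 suits much larger
#' sequence sets) let the pair parameters absorb drift-generated linkage
#' noise, which destroys coupling recovery.
#'
#' @param lambda_main l2 strength on per-site gamma.
#' @param lambda_int l2 strength on pair gamma.
#' @param rho local-consistency penalty multiplier.
#' @param lambda_reg diagonal regularization of the correlation matrix in
#'   the mean-field inversion.
#' @param learning_rate Adam step size.
#' @param max_steps cap on optimization steps.
#' @param early_stop_tol relative loss-change tolerance (used when no
#'   held-out split is available).
#' @param early_stop_window steps over which the relative change is
#'   measured.
#' @param val_fraction fraction of each round's sequences held out for
#'   validation-based early stopping (used when the fit receives raw
#'   sequence data; 0 disables the split).
#' @param val_every evaluate the held-out loss every this many steps.
#' @param val_patience stop after this many consecutive held-out
#'   evaluations without meaningful improvement; the best-validation
#'   parameters are returned.
#' @param val_tol relative held-out improvement below which an
#'   evaluation counts as non-improving.
#' @param pseudocount added to last-round frequencies before the log in
#'   the initialization.
#' @param seed integer recorded in the config (the fit itself is
#'   deterministic).
#' @return object of class `inference_config`.
#' @export
inference_config <- function(lambda_main = 1e-3, lambda_int = 1e-2,
                             rho = 1e5, lambda_reg = 50,
                             learning_rate = 0.03, max_steps = 500L,
                             early_stop_tol = 1e-6, early_stop_window = 10L,
                             val_fraction = 0.1, val_every = 20L,
                             val_patience = 2L, val_tol = 1e-4,
                             pseudocount = 1e-6, seed = 1L) {
  cfg <- list(lambda_main = lambda_main, lambda_int = lambda_int, rho = rho,
              lambda_reg = lambda_reg, learning_rate = learning_rate,
              max_steps = as.integer(max_steps),
              early_stop_tol = early_stop_tol,
              early_stop_window = as.integer(early_stop_window),
              val_fraction = val_fraction,
              val_every = as.integer(val_every),
              val_patience = as.integer(val_patience), val_tol = val_tol,
              pseudocount = pseudocount, seed = as.integer(seed),
              optimizer = "adam")
  stopifnot(all(vapply(cfg[1:13], function(x) is.numeric(x) && x >= 0,
                       logical(1))), val_fraction < 1)
  structure(cfg, class = "inference_config")
}

# amino-acid expansion helpers ----------------------------------------------

.aa_expand <- function() {
  if (is.null(.pkg_env$aa_expand)) {
    ab <- codon_alphabet()
    .pkg_env$aa_expand <- list(
      ac = ab$ac_map,
      mult = as.numeric(ab$multiplicity),
      idx400 = as.vector(outer(ab$ac_map, 20L * (ab$ac_map - 1L), "+")),
      w400 = as.vector(outer(ab$multiplicity, ab$multiplicity)))
  }
  .pkg_env$aa_expand
}

.softmax_rows <- function(g) {
  e <- exp(g - apply(g, 1L, max))
  e / rowSums(e)
}

.softmax_cols <- function(g) {
  e <- exp(g - rep(apply(g, 2L, max), each = nrow(g)))
  e / rep(colSums(e), each = nrow(g))
}

#' Gamma parameters
#'
#' @param first L x 20 matrix gamma_i(a).
#' @param second 400 x npairs matrix; column p is the vectorized 20 x 20
#'   block gamma_ij(a, b) (entry (a, b) at row `a + 20 * (b - 1)`).
#' @param pairs pair matrix (i < j) matching `second`.
#' @return object of class `gamma_params`.
#' @export
gamma_params <- function(first, second = NULL, pairs = NULL) {
  stopifnot(is.matrix(first), ncol(first) == 20L, all(is.finite(first)))
  if (!is.null(second)) {
    if (is.null(pairs)) pairs <- all_pairs(nrow(first))
    stopifnot(nrow(second) == 400L, ncol(second) == nrow(pairs),
              all(is.finite(second)))
  }
  structure(list(first = first, second = second, pairs = pairs),
            class = "gamma_params")
}

#' Amino-acid and codon marginals implied by gamma
#'
#' Per-site and per-pair softmaxes give amino-acid marginals nu; codon
#' marginals divide each amino acid's mass equally among its synonymous
#' codons, so the synonymous-uniformity constraint holds by construction.
#'
#' @param gamma a [gamma_params].
#' @return list with `nu_first` (L x 20), `mu_first` (L x 61),
#'   `S_first` (per-site codon-normalizers), and when pair blocks are
#'   present `nu_second` (400 x npairs), `mu_second` (3721 x npairs),
#'   `S_second`, `pairs`.
#' @export
gamma_to_marginals <- function(gamma) {
  ex <- .aa_expand()
  nu1 <- .softmax_rows(gamma$first)
  S1 <- as.vector(nu1 %*% ex$mult)
  mu1 <- nu1[, ex$ac, drop = FALSE] / S1
  out <- list(nu_first = nu1, mu_first = mu1, S_first = S1,
              pairs = gamma$pairs)
  if (!is.null(gamma$second)) {
    nu2 <- .softmax_cols(gamma$second)
    S2 <- as.vector(crossprod(nu2, ex$w400))
    mu2 <- nu2[ex$idx400, , drop = FALSE] / rep(S2, each = 3721L)
    out$nu_second <- nu2; out$mu_second <- mu2; out$S_second <- S2
  }
  out
}

# empirical codon frequencies -> amino-acid frequencies
.aa_frequencies <- function(freq) {
  ex <- .aa_expand()
  out <- list(first = t(rowsum(t(freq$first), ex$ac)))
  if (!is.null(freq$second))
    out$second <- rowsum(freq$second, ex$idx400)
  out
}

# penalty residual r_ia = nu_i(a) - mean_j sum_b nu_ij(a, b)
.penalty_residual <- function(nu1, nu2, pairs) {
  L <- nrow(nu1)
  acc <- matrix(0, L, 20L)
  for (p in seq_len(nrow(pairs))) {
    blk <- matrix(nu2[, p], 20L, 20L)
    acc[pairs[p, 1], ] <- acc[pairs[p, 1], ] + rowSums(blk)
    acc[pairs[p, 2], ] <- acc[pairs[p, 2], ] + colSums(blk)
  }
  nu1 - acc / (L - 1)
}

#' Trajectory moment-matching loss (and its gradient)
#'
#' Chains the wild-type delta initialization through the recursive moment
#' propagation under the landscape marginals implied by `gamma`, and
#' aggregates the log-loss of empirical versus predicted first- and
#' second-order codon frequencies over all sequenced rounds (pair terms
#' count both orders i != j), plus the l2 regularizers and the quadratic
#' local-consistency penalty.
#'
#' @param gamma a [gamma_params].
#' @param data named list of empirical [moment_vector]s, names = round
#'   indices (from [empirical_frequencies]).
#' @param model a `mutation_model`.
#' @param wildtype integer codon-index vector.
#' @param config an [inference_config].
#' @param gradient also return analytic gradients (default TRUE).
#' @return list with `loss`, `pieces` (data/penalty/regularizer
#'   decomposition) and, if requested, `grad` (a [gamma_params]-shaped
#'   list).
#' @export
trajectory_loss <- function(gamma, data, model, wildtype, config,
                            gradient = TRUE) {
  if (length(data) == 0L) stop("no sequenced rounds", call. = FALSE)
  rounds <- as.integer(names(data))
  stopifnot(!anyNA(rounds), all(rounds >= 0L))
  use <- rounds >= 1L
  data <- data[use]; rounds <- rounds[use]
  Rmax <- max(rounds)
  L <- nrow(gamma$first)
  stopifnot(length(wildtype) == L, is.null(model$per_position))
  K <- model$kernel
  marg <- gamma_to_marginals(gamma)
  M1 <- marg$mu_first
  pairwise <- !is.null(gamma$second)
  P0 <- init_moments(wildtype, second = pairwise)

  # forward: predicted moments round 0..Rmax (first order in R; the
  # pairwise recursion runs in compiled code, forward and backward in one
  # pass)
  D1 <- M1 %*% t(K)
  P1 <- vector("list", Rmax + 1L); P1[[1L]] <- P0$first
  for (r in seq_len(Rmax)) {
    W <- P1[[r]] / D1
    P1[[r + 1L]] <- M1 * (W %*% K)
  }
  loss_data <- 0
  for (k in seq_along(rounds)) {
    f <- data[[k]]
    loss_data <- loss_data - sum(f$first * log(pmax(P1[[rounds[k] + 1L]],
                                                    1e-300)))
  }
  if (pairwise) {
    M2 <- marg$mu_second
    wtpair <- (wildtype[gamma$pairs[, 1]] - 1L) +
      61L * (wildtype[gamma$pairs[, 2]] - 1L)
    pw <- pair_forward_backward(K, M2, wtpair,
                                lapply(data, `[[`, "second"),
                                rounds, Rmax, gradient)
    loss_data <- loss_data + pw$loss
  }
  r_main <- sum(gamma$first^2)
  r_int <- if (pairwise) 2 * sum(gamma$second^2) else 0
  if (pairwise) {
    pen_res <- .penalty_residual(marg$nu_first, marg$nu_second, gamma$pairs)
    pen <- sum(pen_res^2)
  } else {
    pen_res <- NULL; pen <- 0
  }
  loss <- loss_data + config$lambda_main * r_main +
    config$lambda_int * r_int + config$rho * pen
  out <- list(loss = loss,
              pieces = c(data = loss_data, penalty = pen,
                         r_main = r_main, r_int = r_int))
  if (!gradient) return(out)

  # backward through the first-order recursion (the pairwise M2bar came
  # back from the compiled pass)
  ex <- .aa_expand()
  G1 <- matrix(0, L, 61L)
  M1bar <- matrix(0, L, 61L)
  for (r in Rmax:1L) {
    k <- match(r, rounds)
    if (!is.na(k))
      G1 <- G1 - data[[k]]$first / pmax(P1[[r + 1L]], 1e-300)
    V <- (G1 * M1) %*% t(K)
    M1bar <- M1bar + G1 * (P1[[r + 1L]] / M1) -
      ((P1[[r]] * V) / D1^2) %*% K
    G1 <- V / D1
  }
  if (pairwise) M2bar <- pw$M2bar

  # chain codon-marginal gradients to nu, add penalty, then to gamma
  T1 <- t(rowsum(t(M1bar), ex$ac))                     # L x 20
  q1 <- rowSums(M1bar * M1)
  nu1bar <- (T1 - outer(q1, ex$mult)) / marg$S_first
  if (pairwise) nu1bar <- nu1bar + 2 * config$rho * pen_res
  nu1 <- marg$nu_first
  gfirst <- nu1 * (nu1bar - rowSums(nu1bar * nu1)) +
    2 * config$lambda_main * gamma$first

  gsecond <- NULL
  if (pairwise) {
    T2 <- rowsum(M2bar, ex$idx400)                     # 400 x npairs
    q2 <- colSums(M2bar * M2)
    nu2bar <- (T2 - outer(ex$w400, q2)) /
      rep(marg$S_second, each = 400L)
    fac <- -2 * config$rho / (L - 1)
    for (p in seq_len(nrow(gamma$pairs))) {
      i <- gamma$pairs[p, 1]; j <- gamma$pairs[p, 2]
      nu2bar[, p] <- nu2bar[, p] +
        fac * (rep(pen_res[i, ], 20L) + rep(pen_res[j, ], each = 20L))
    }
    nu2 <- marg$nu_second
    inner <- colSums(nu2bar * nu2)
    gsecond <- nu2 * (nu2bar - rep(inner, each = 400L)) +
      4 * config$lambda_int * gamma$second
  }
  out$grad <- list(first = gfirst, second = gsecond)
  out
}

#' Fit the landscape's mean parameters by moment matching
#'
#' Runs Adam on [trajectory_loss] from the documented initialization (log
#' of the last sequenced round's amino-acid frequencies plus a
#' pseudocount). Early stopping: when raw sequence data are available, a
#' fraction of each round's sequences is held out and optimization stops
#' once the held-out log-loss stops improving, returning the
#' best-validation parameters — the trajectory likelihood keeps
#' decreasing long after the pair parameters have started absorbing
#' per-round sampling noise, so a training-loss plateau rule stops far
#' too late. When only frequency tables are supplied the plateau rule on
#' the training loss is used instead. Deterministic given the
#' configuration.
#'
#' @param data a [trajectory_dataset], or a named list of empirical
#'   [moment_vector]s (names = round indices; disables the held-out
#'   split).
#' @param model a `mutation_model`.
#' @param wildtype integer codon-index vector (defaults to the dataset's).
#' @param config an [inference_config].
#' @param pairwise fit pair blocks too (default TRUE; FALSE gives an
#'   independent-site fit).
#' @param verbose print the loss every 25 steps.
#' @return object of class `mean_fit`: `gamma`, `marginals` (nu/mu),
#'   `loss_trace`, `val_trace` (held-out evaluations, if any), `config`,
#'   `steps`, `best_step`, `initial_loss`.
#' @export
fit_mean_parameters <- function(data, model, wildtype = NULL,
                                config = inference_config(),
                                pairwise = TRUE, verbose = FALSE) {
  val_data <- NULL
  if (inherits(data, "trajectory_dataset")) {
    if (is.null(wildtype)) wildtype <- data$wildtype
    if (config$val_fraction > 0) {
      set.seed(config$seed)
      train <- list(); val <- list()
      for (k in seq_along(data$rounds)) {
        s <- data$rounds[[k]]
        n <- nrow(s$seqs)
        n_val <- max(1L, floor(config$val_fraction * n))
        if (n_val >= n) { n_val <- 0L }
        idx <- sample.int(n, n_val)
        if (n_val > 0L) {
          val[[names(data$rounds)[k]]] <-
            empirical_frequencies(round_sample(s$seqs[idx, , drop = FALSE],
                                               s$round), second = pairwise)
          train[[names(data$rounds)[k]]] <-
            empirical_frequencies(round_sample(s$seqs[-idx, , drop = FALSE],
                                               s$round), second = pairwise)
        } else {
          train[[names(data$rounds)[k]]] <-
            empirical_frequencies(s, second = pairwise)
        }
      }
      data <- train
      if (length(val)) val_data <- val
    } else {
      freqs <- lapply(data$rounds, empirical_frequencies, second = pairwise)
      names(freqs) <- names(data$rounds)
      data <- freqs
    }
  }
  if (length(data) == 0L) stop("no sequenced rounds", call. = FALSE)
  stopifnot(!is.null(wildtype))

  last <- data[[which.max(as.integer(names(data)))]]
  faa <- .aa_frequencies(last)
  g1 <- log(faa$first + config$pseudocount)
  g2 <- if (pairwise) log(faa$second + config$pseudocount) else NULL
  gamma <- gamma_params(g1, g2)

  # Adam state
  lr <- config$learning_rate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  m1 <- 0 * g1; v1 <- 0 * g1
  if (pairwise) { m2 <- 0 * g2; v2 <- 0 * g2 }
  trace <- numeric(0)
  val_trace <- numeric(0)
  win <- config$early_stop_window
  best_val <- Inf; best_gamma <- gamma; best_step <- 0L; stale <- 0L
  for (step in seq_len(config$max_steps)) {
    res <- trajectory_loss(gamma, data, model, wildtype, config)
    if (!is.finite(res$loss))
      stop(sprintf("divergent loss at step %d (|gamma1| = %.3g, |gamma2| = %.3g)",
                   step, sqrt(sum(gamma$first^2)),
                   if (pairwise) sqrt(sum(gamma$second^2)) else 0),
           call. = FALSE)
    trace <- c(trace, res$loss)
    if (verbose && step %% 25L == 1L)
      message(sprintf("step %d: loss %.6g", step, res$loss))
    g <- res$grad
    m1 <- b1 * m1 + (1 - b1) * g$first
    v1 <- b2 * v1 + (1 - b2) * g$first^2
    gamma$first <- gamma$first -
      lr * (m1 / (1 - b1^step)) / (sqrt(v1 / (1 - b2^step)) + eps)
    if (pairwise) {
      m2 <- b1 * m2 + (1 - b1) * g$second
      v2 <- b2 * v2 + (1 - b2) * g$second^2
      gamma$second <- gamma$second -
        lr * (m2 / (1 - b1^step)) / (sqrt(v2 / (1 - b2^step)) + eps)
    }
    if (!is.null(val_data)) {
      if (step %% config$val_every == 0L) {
        vl <- trajectory_loss(gamma, val_data, model, wildtype, config,
                              gradient = FALSE)$pieces[["data"]]
        val_trace <- c(val_trace, vl)
        if (verbose)
          message(sprintf("step %d: held-out loss %.6g", step, vl))
        improved <- !is.finite(best_val) ||
          vl < best_val - config$val_tol * abs(best_val)
        if (vl < best_val) {
          best_val <- vl; best_gamma <- gamma; best_step <- step
        }
        if (improved) {
          stale <- 0L
        } else {
          stale <- stale + 1L
          if (stale >= config$val_patience) break
        }
      }
    } else if (step > win) {
      prev <- trace[step - win]
      if (abs(prev - res$loss) < config$early_stop_tol * abs(prev)) break
    }
  }
  if (!is.null(val_data) && best_step > 0L) gamma <- best_gamma
  final <- trajectory_loss(gamma, data, model, wildtype, config,
                           gradient = FALSE)
  trace <- c(trace, final$loss)
  structure(list(gamma = gamma, marginals = gamma_to_marginals(gamma),
                 loss_trace = trace, val_trace = val_trace, config = config,
                 steps = length(trace) - 1L,
                 best_step = if (!is.null(val_data)) best_step else
                   length(trace) - 1L,
                 initial_loss = trace[1]),
            class = "mean_fit")
}

#' @export
print.mean_fit <- function(x, ...) {
  cat(sprintf("mean_fit: %d optimization steps, loss %.6g -> %.6g\n",
              x$steps, x$initial_loss, x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

#' Mean-field inversion of fitted marginals to canonical Potts parameters
#'
#' Builds the connected-correlation matrix C over the `L * 19` non-reference
#' amino-acid dimensions (reference state per site: the wild-type amino
#' acid), adds `lambda_reg` to its diagonal, and sets the couplings to
#' `-(C + lambda I)^{-1}` reshaped into pair blocks. Fields come from the
#' mean-field self-consistency relation
#' `h_i(a) = log(nu_i(a)/nu_i(ref)) - sum_(j != i, b) e_ij(a, b) nu_j(b)`.
#'
#' @param marginals amino-acid marginals: a list with `nu_first`
#'   (L x 20), `nu_second` (400 x npairs over all pairs) and `pairs`
#'   (e.g. a `mean_fit$marginals`).
#' @param lambda_reg diagonal regularization (default 50).
#' @param ref integer vector of reference amino-acid indices per site
#'   (usually the wild-type); defaults to each site's most probable amino
#'   acid.
#' @return a [potts_model] with couplings on every pair.
#' @export
invert_to_canonical <- function(marginals, lambda_reg = 50, ref = NULL) {
  nu1 <- marginals$nu_first
  nu2 <- marginals$nu_second
  pairs <- marginals$pairs
  L <- nrow(nu1)
  np <- nrow(pairs)
  stopifnot(np == choose(L, 2))
  if (is.null(ref)) ref <- max.col(nu1, ties.method = "first")
  ref <- as.integer(ref)
  keep <- lapply(seq_len(L), function(i) setdiff(1:20, ref[i]))
  d <- 19L
  C <- matrix(0, L * d, L * d)
  blockrows <- function(i) ((i - 1L) * d + 1L):(i * d)
  for (i in seq_len(L)) {
    v <- nu1[i, keep[[i]]]
    C[blockrows(i), blockrows(i)] <- diag(v, d) - tcrossprod(v)
  }
  for (p in seq_len(np)) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    blk <- matrix(nu2[, p], 20L, 20L)[keep[[i]], keep[[j]]] -
      tcrossprod(nu1[i, keep[[i]]], nu1[j, keep[[j]]])
    C[blockrows(i), blockrows(j)] <- blk
    C[blockrows(j), blockrows(i)] <- t(blk)
  }
  Creg <- C + diag(lambda_reg, L * d)
  Einv <- tryCatch(-solve(Creg), error = function(e)
    stop("correlation matrix numerically singular; increase lambda_reg",
         call. = FALSE))
  blocks <- array(0, c(20L, 20L, np))
  for (p in seq_len(np)) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    blocks[keep[[i]], keep[[j]], p] <- Einv[blockrows(i), blockrows(j)]
  }
  h <- matrix(0, L, 20L)
  nu_safe <- pmax(nu1, 1e-12)
  for (i in seq_len(L)) {
    h[i, ] <- log(nu_safe[i, ] / nu_safe[i, ref[i]])
    for (p in which(pairs[, 1] == i | pairs[, 2] == i)) {
      j <- sum(pairs[p, ]) - i
      eij <- blocks[, , p]
      if (pairs[p, 2] == i) eij <- t(eij)   # orient as e_i,j(a, b)
      h[i, ] <- h[i, ] - as.vector(eij %*% nu1[j, ])
    }
  }
  potts_model(h, pairs, blocks)
}
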