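# Potts fitness landscape over amino acids: per-site fields h_i(a) and
# pairwise couplings e_ij(a,b) for i<j. The model stores log-fitness; the
# normalizing constant of the sequence distribution is never computed and
# every downstream use (dynamics, walks, epistasis) relies on score
# differences only.

#' Construct a Potts fitness landscape
#'
#' @param h L x 20 matrix of main-effect parameters `h_i(a)`, columns in
#'   the order of `codon_alphabet()$amino_acids`.
#' @param coupling_pairs integer matrix with 2 columns (i, j), i < j, one
#'   row per coupled pair; `NULL` for a coupling-free (additive) model.
#' @param coupling_blocks numeric array `c(20, 20, npairs)`;
#'   `coupling_blocks[a, b, p]` is `e_ij(a, b)` for the p-th pair. Access
#'   for j > i is symmetrized: `e_ji(b, a) = e_ij(a, b)`.
#' @param offset scalar added to every score (bookkeeping for gauge
#'   transforms that absorb constants; irrelevant to score differences).
#' @return object of class `potts_model` with fields `L`, `h`, `pairs`,
#'   `blocks`, `pair_id` (L x L lookup, 0 = uncoupled), `offset`.
#' @export
potts_model <- function(h, coupling_pairs = NULL, coupling_blocks = NULL,
                        offset = 0) {
  stopifnot(is.matrix(h), ncol(h) == 20L, all(is.finite(h)))
  L <- nrow(h)
  pair_id <- matrix(0L, L, L)
  if (!is.null(coupling_pairs)) {
    coupling_pairs <- matrix(as.integer(coupling_pairs), ncol = 2L)
    stopifnot(all(coupling_pairs[, 1] < coupling_pairs[, 2]),
              all(coupling_pairs >= 1L), all(coupling_pairs <= L))
    np <- nrow(coupling_pairs)
    stopifnot(is.array(coupling_blocks),
              all(dim(coupling_blocks) == c(20L, 20L, np)),
              all(is.finite(coupling_blocks)))
    if (anyDuplicated(coupling_pairs)) stop("duplicate coupling pairs", call. = FALSE)
    pair_id[coupling_pairs] <- seq_len(np)
    pair_id[coupling_pairs[, 2:1, drop = FALSE]] <- seq_len(np)
  } else {
    coupling_blocks <- array(0, c(20L, 20L, 0L))
    coupling_pairs <- matrix(integer(0), ncol = 2L)
  }
  structure(list(L = L, h = h, pairs = coupling_pairs,
                 blocks = coupling_blocks, pair_id = pair_id,
                 offset = as.numeric(offset)),
            class = "potts_model")
}

#' @export
print.potts_model <- function(x, ...) {
  cat(sprintf("potts_model: L = %d residues, %d coupled pair(s)\n",
              x$L, nrow(x$pairs)))
  invisible(x)
}

# coerce amino-acid input (string(s), index vector, or n x L index matrix)
.aa_matrix <- function(seq, L) {
  if (is.character(seq)) seq <- do.call(rbind, lapply(seq, aa_index))
  if (is.vector(seq)) seq <- matrix(as.integer(seq), nrow = 1L)
  if (ncol(seq) != L) stop("sequence length mismatch", call. = FALSE)
  storage.mode(seq) <- "integer"
  seq
}

#' Log-fitness score of amino-acid sequences
#'
#' `sum_i h_i(a_i) + sum_(i<j) e_ij(a_i, a_j)` (+ the model's offset).
#' Differences of scores equal log relative-fitness ratios; absolute
#' values carry no meaning because the landscape normalization is never
#' evaluated.
#'
#' @param model a [potts_model].
#' @param seq amino-acid string(s), an index vector, or an n x L index
#'   matrix.
#' @return numeric vector of scores, one per sequence.
#' @export
score_sequences <- function(model, seq) {
  aa <- .aa_matrix(seq, model$L)
  n <- nrow(aa)
  L <- model$L
  sc <- rowSums(matrix(model$h[as.vector(col(aa) + (aa - 1L) * L)], n, L)) +
    model$offset
  np <- nrow(model$pairs)
  if (np > 0L) {
    for (p in seq_len(np)) {
      i <- model$pairs[p, 1]; j <- model$pairs[p, 2]
      sc <- sc + model$blocks[cbind(aa[, i], aa[, j], p)]
    }
  }
  sc
}

#' Single-mutant effect map around a wild-type sequence
#'
#' Entry (i, a) is the score change of substituting amino acid a at
#' position i into the wild-type background; wild-type entries are 0.
#'
#' @param model a [potts_model].
#' @param wt wild-type amino-acid string or index vector (length L).
#' @return L x 20 matrix of score changes, rows named by 1-based position,
#'   columns by amino acid.
#' @export
mutation_effect_map <- function(model, wt) {
  aa <- as.integer(.aa_matrix(wt, model$L))
  L <- model$L
  d <- model$h - model$h[cbind(seq_len(L), aa)]
  np <- nrow(model$pairs)
  if (np > 0L) {
    for (p in seq_len(np)) {
      i <- model$pairs[p, 1]; j <- model$pairs[p, 2]
      blk <- model$blocks[, , p]
      d[i, ] <- d[i, ] + blk[, aa[j]] - blk[aa[i], aa[j]]
      d[j, ] <- d[j, ] + blk[aa[i], ] - blk[aa[i], aa[j]]
    }
  }
  ab <- codon_alphabet()
  dimnames(d) <- list(seq_len(L), ab$amino_acids)
  d
}

#' Convert couplings to the zero-sum gauge
#'
#' Each 20 x 20 coupling block is centred so that all of its row and
#' column sums vanish:
#' `e'(a,b) = e(a,b) - mean_b e(a,.) - mean_a e(.,b) + mean e(.,.)`.
#' With `absorb = TRUE` the removed row/column means are moved into the
#' fields (and the grand means into the model offset), so every sequence
#' score is exactly preserved; with `absorb = FALSE` only the couplings
#' are replaced.
#'
#' @param model a [potts_model].
#' @param absorb move removed means into `h` and `offset` (default TRUE).
#' @return a [potts_model] whose coupling blocks are zero-sum gauged.
#' @export
zero_sum_gauge <- function(model, absorb = TRUE) {
  np <- nrow(model$pairs)
  if (np == 0L) return(model)
  h <- model$h
  off <- model$offset
  blocks <- model$blocks
  for (p in seq_len(np)) {
    blk <- blocks[, , p]
    rm_ <- rowMeans(blk); cm_ <- colMeans(blk); gm <- mean(blk)
    blocks[, , p] <- blk - outer(rm_, rep(1, 20)) - outer(rep(1, 20), cm_) + gm
    if (absorb) {
      i <- model$pairs[p, 1]; j <- model$pairs[p, 2]
      h[i, ] <- h[i, ] + rm_ - gm / 2
      h[j, ] <- h[j, ] + cm_ - gm / 2
      # rm(a) + cm(b) - gm was removed from the block; rm - gm/2 and
      # cm - gm/2 restore it exactly for every (a, b)
    }
  }
  potts_model(h, model$pairs, blocks, offset = off)
}

#' Residue-residue interaction scores (Frobenius norms)
#'
#' Converts couplings to the zero-sum gauge and takes the Frobenius norm
#' `F_ij = ||e'_ij||` of each block. Pairs closer than or equal to
#' `min_separation` positions are flagged short-range and excluded from
#' rankings and contact evaluation.
#'
#' @param model a [potts_model].
#' @param min_separation pairs with `|i - j| <= min_separation` are
#'   short-range (default 5, i.e. only pairs differing by more than 5
#'   positions are ranked).
#' @return object of class `interaction_scores`: list with `F` (symmetric
#'   L x L matrix, zero diagonal), `long_range` (logical L x L mask) and
#'   `min_separation`.
#' @export
interaction_scores <- function(model, min_separation = 5) {
  g <- zero_sum_gauge(model, absorb = FALSE)
  L <- model$L
  F <- matrix(0, L, L)
  np <- nrow(g$pairs)
  if (np > 0L) {
    fn <- sqrt(apply(g$blocks^2, 3L, sum))
    F[g$pairs] <- fn
    F[g$pairs[, 2:1, drop = FALSE]] <- fn
  }
  sep <- abs(row(F) - col(F))
  structure(list(F = F, long_range = sep > min_separation,
                 min_separation = min_separation),
            class = "interaction_scores")
}

#' @export
print.interaction_scores <- function(x, ...) {
  lr <- x$F[upper.tri(x$F) & x$long_range]
  cat(sprintf("interaction_scores: L = %d, %d long-range pairs (separation > %d), max F = %.4g\n",
              nrow(x$F), length(lr), x$min_separation,
              if (length(lr)) max(lr) else 0))
  invisible(x)
}

#' Rank long-range pairs by interaction score
#' @param scores an [interaction_scores] object.
#' @return data.frame (i, j, F) sorted by decreasing F, long-range pairs
#'   only, ties broken by (i, j) order.
#' @export
top_interactions <- function(scores) {
  F <- scores$F
  sel <- which(upper.tri(F) & scores$long_range, arr.ind = TRUE)
  out <- data.frame(i = sel[, 1], j = sel[, 2], F = F[sel])
  out[order(-out$F, out$i, out$j), , drop = FALSE]
}

#' Classify pairwise epistasis of all double mutants of a wild-type
#'
#' For every unordered position pair (i < j) and mutant amino-acid pair
#' (a != wt_i, b != wt_j), let dA be the effect of a at i in the wild-type
#' background, dB likewise, and dA|B, dB|A the same effects in the
#' background carrying the other mutation. The pair is
#' *reciprocal-sign* epistatic if both effects flip sign in the other's
#' background, *sign* epistatic if exactly one flips, and *additive*
#' otherwise. Effects of magnitude below `tol` are treated as zero and
#' never count as flips.
#'
#' Because only the (i, j) coupling block differs between the backgrounds,
#' dA|B - dA = dB|A - dB = eps(a, b), the double-mutant coupling
#' increment; uncoupled pairs are therefore always additive and are
#' counted without enumeration.
#'
#' @param model a [potts_model].
#' @param wt wild-type amino-acid string or index vector.
#' @param tol zero-effect tolerance (default 1e-9).
#' @return object of class `epistasis_counts`: list with `counts`
#'   (named vector: additive, sign, reciprocal_sign, total), and
#'   `reciprocal` (data.frame i, j, mut_i, mut_j, dA, dB, dAB, dBA with
#'   mutations named like "K47A").
#' @export
classify_epistasis <- function(model, wt, tol = 1e-9) {
  aa <- as.integer(.aa_matrix(wt, model$L))
  L <- model$L
  ab <- codon_alphabet()
  d <- mutation_effect_map(model, aa)
  total <- choose(L, 2) * 19^2
  n_sign <- 0; n_recip <- 0
  rec <- list()
  sgn <- function(x) ifelse(abs(x) < tol, 0L, as.integer(sign(x)))
  np <- nrow(model$pairs)
  for (p in seq_len(np)) {
    i <- model$pairs[p, 1]; j <- model$pairs[p, 2]
    ai <- setdiff(1:20, aa[i]); bj <- setdiff(1:20, aa[j])
    blk <- model$blocks[, , p]
    eps <- blk[ai, bj, drop = FALSE] -
      outer(blk[ai, aa[j]], rep(1, 19)) -
      outer(rep(1, 19), blk[aa[i], bj]) + blk[aa[i], aa[j]]
    dA <- matrix(d[i, ai], 19, 19)
    dB <- matrix(d[j, bj], 19, 19, byrow = TRUE)
    sA <- sgn(dA); sB <- sgn(dB)
    sAB <- sgn(dA + eps); sBA <- sgn(dB + eps)
    flipA <- sA != 0L & sAB == -sA
    flipB <- sB != 0L & sBA == -sB
    recip <- flipA & flipB
    n_recip <- n_recip + sum(recip)
    n_sign <- n_sign + sum(xor(flipA, flipB))
    if (any(recip)) {
      w <- which(recip, arr.ind = TRUE)
      rec[[length(rec) + 1L]] <- data.frame(
        i = i, j = j,
        mut_i = paste0(ab$amino_acids[aa[i]], i, ab$amino_acids[ai[w[, 1]]]),
        mut_j = paste0(ab$amino_acids[aa[j]], j, ab$amino_acids[bj[w[, 2]]]),
        dA = dA[w], dB = dB[w], dAB = (dA + eps)[w], dBA = (dB + eps)[w])
    }
  }
  counts <- c(additive = total - n_sign - n_recip, sign = n_sign,
              reciprocal_sign = n_recip, total = total)
  structure(list(counts = counts,
                 reciprocal = if (length(rec)) do.call(rbind, rec) else
                   data.frame(i = integer(0), j = integer(0),
                              mut_i = character(0), mut_j = character(0),
                              dA = numeric(0), dB = numeric(0),
                              dAB = numeric(0), dBA = numeric(0)),
                 tol = tol),
            class = "epistasis_counts")
}

#' @export
print.epistasis_counts <- function(x, ...) {
  cat("epistasis classification of double mutants:\n")
  print(x$counts)
  invisible(x)
}

# Serialization -------------------------------------------------------------

#' Write / read a Potts model as JSON
#'
#' The container records a version tag, the alphabet order, L, the fields
#' and the upper-triangular coupling pairs/blocks; round-trips exactly to
#' numeric precision of the JSON writer (digits = NA keeps full
#' precision).
#'
#' @param model a [potts_model].
#' @param path output path.
#' @return `path` (write) or the restored [potts_model] (read).
#' @export
write_potts <- function(model, path) {
  obj <- list(format = "evoscape-potts", version = 1L,
              amino_acids = codon_alphabet()$amino_acids,
              L = model$L, h = model$h, offset = model$offset,
              pairs = model$pairs,
              blocks = if (nrow(model$pairs)) model$blocks else NULL)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_potts
#' @export
read_potts <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "evoscape-potts"))
    stop("not an evoscape Potts container", call. = FALSE)
  h <- matrix(as.numeric(obj$h), obj$L, 20L)
  if (is.null(obj$blocks) || length(obj$blocks) == 0L)
    return(potts_model(h, offset = obj$offset))
  pairs <- matrix(as.integer(obj$pairs), ncol = 2L)
  blocks <- array(as.numeric(obj$blocks), c(20L, 20L, nrow(pairs)))
  potts_model(h, pairs, blocks, offset = obj$offset)
}
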