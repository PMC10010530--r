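# Landscape exploration and evaluation: greedy adaptive walks (single or
# single+double mutant move sets), surveys of walk convergence from random
# starts, and contact-map positive predictive value of the Frobenius
# interaction ranking.

# best strictly-improving move given the current single-mutant delta map
# tie rule: single moves beat equal-scoring double moves; then lowest
# position index, then alphabetical amino acid.
.best_single <- function(d) {
  m <- max(d)
  if (m <= 0) return(NULL)
  w <- which(d == m, arr.ind = TRUE)
  w <- w[order(w[, 1], w[, 2]), , drop = FALSE]
  list(gain = m, pos = w[1, 1], aa = w[1, 2])
}

#' Greedy adaptive walk to a local fitness peak
#'
#' Steepest-ascent hill climbing: at each step all moves in the move set
#' (all single mutants, or all single and double mutants) are evaluated
#' and the best strictly-improving one is accepted, until no move improves
#' or `max_steps` is reached. Ties are broken deterministically: single
#' moves before equal-scoring double moves, then lowest position, then
#' alphabetical amino acid.
#'
#' @param landscape a [potts_model].
#' @param start amino-acid string or index vector of length L.
#' @param moves `"single"` or `"single+double"`.
#' @param max_steps cap on accepted moves.
#' @return object of class `adaptive_walk`: `start`, `endpoint` (index
#'   vector), `scores` (score after each accepted move, strictly
#'   increasing), `steps` (data.frame: positions and substitutions),
#'   `start_score`, `moves`.
#' @export
adaptive_walk <- function(landscape, start, moves = c("single", "single+double"),
                          max_steps = 10000L) {
  moves <- match.arg(moves)
  cur <- as.integer(.aa_matrix(start, landscape$L))
  L <- landscape$L
  ab <- codon_alphabet()
  score <- score_sequences(landscape, cur)
  start_score <- score
  scores <- numeric(0)
  steps <- list()
  repeat {
    if (length(scores) >= max_steps) break
    d <- mutation_effect_map(landscape, cur)
    d[cbind(seq_len(L), cur)] <- 0
    best1 <- .best_single(d)
    best <- NULL
    if (!is.null(best1))
      best <- list(gain = best1$gain, pos = c(best1$pos), aa = c(best1$aa))
    if (moves == "single+double") {
      bestd <- .best_double(landscape, cur, d)
      if (!is.null(bestd) && (is.null(best) || bestd$gain > best$gain))
        best <- bestd
    }
    if (is.null(best)) break
    from <- cur[best$pos]
    cur[best$pos] <- best$aa
    score <- score + best$gain
    scores <- c(scores, score)
    steps[[length(steps) + 1L]] <- data.frame(
      step = length(scores),
      mutation = paste(ab$amino_acids[from], best$pos,
                       ab$amino_acids[best$aa], sep = "", collapse = "+"),
      n_subs = length(best$pos), score = score)
  }
  structure(list(start = as.integer(.aa_matrix(start, L)), endpoint = cur,
                 scores = scores, start_score = start_score,
                 steps = if (length(steps)) do.call(rbind, steps) else
                   data.frame(step = integer(0), mutation = character(0),
                              n_subs = integer(0), score = numeric(0)),
                 moves = moves),
            class = "adaptive_walk")
}

# best strictly-improving double move: for uncoupled position pairs the
# gain separates into the two best single gains (found exactly over all
# uncoupled pairs); coupled pairs add the double-mutant coupling
# increment and are enumerated block-wise.
.best_double <- function(landscape, cur, d) {
  L <- landscape$L
  d <- d
  d[cbind(seq_len(L), cur)] <- -Inf       # a double move changes both sites
  rowbest <- apply(d, 1L, max)
  best <- NULL
  if (L >= 2L) {
    S <- outer(rowbest, rowbest, "+")
    S[lower.tri(S, diag = TRUE)] <- -Inf
    S[landscape$pair_id > 0L] <- -Inf     # coupled pairs handled exactly below
    m <- suppressWarnings(max(S))
    if (is.finite(m) && m > 0) {
      w <- which(S == m, arr.ind = TRUE)
      w <- w[order(w[, 1], w[, 2]), , drop = FALSE]
      i <- w[1, 1]; j <- w[1, 2]
      best <- list(gain = m, pos = c(i, j),
                   aa = c(which(d[i, ] == rowbest[i])[1],
                          which(d[j, ] == rowbest[j])[1]))
    }
  }
  np <- nrow(landscape$pairs)
  for (p in seq_len(np)) {
    i <- landscape$pairs[p, 1]; j <- landscape$pairs[p, 2]
    blk <- landscape$blocks[, , p]
    eps <- blk - outer(blk[, cur[j]], rep(1, 20)) -
      outer(rep(1, 20), blk[cur[i], ]) + blk[cur[i], cur[j]]
    tot <- outer(d[i, ], d[j, ], "+") + eps
    tot[cur[i], ] <- -Inf; tot[, cur[j]] <- -Inf
    m <- max(tot)
    if (m > 0 && (is.null(best) || m > best$gain)) {
      w <- which(tot == m, arr.ind = TRUE)
      w <- w[order(w[, 1], w[, 2]), , drop = FALSE]
      best <- list(gain = m, pos = c(i, j), aa = c(w[1, 1], w[1, 2]))
    }
  }
  best
}

#' @export
print.adaptive_walk <- function(x, ...) {
  cat(sprintf("adaptive_walk (%s moves): %d accepted step(s), score %.4g -> %.4g\n",
              x$moves, length(x$scores), x$start_score,
              if (length(x$scores)) x$scores[length(x$scores)] else x$start_score))
  invisible(x)
}

#' Verify a sequence is a local optimum of the single-mutant neighborhood
#' @param landscape a [potts_model].
#' @param seq amino-acid index vector or string.
#' @return TRUE if no single mutant strictly improves the score.
#' @export
is_local_peak <- function(landscape, seq) {
  cur <- as.integer(.aa_matrix(seq, landscape$L))
  d <- mutation_effect_map(landscape, cur)
  d[cbind(seq_len(landscape$L), cur)] <- 0
  max(d) <= 0
}

#' Survey adaptive-walk convergence from random starts
#'
#' Draws `n_starts` uniform random amino-acid sequences, runs a
#' single-mutant adaptive walk from each, and tabulates the unique
#' endpoints with their basin counts and (optionally) Hamming distance to
#' a reference sequence.
#'
#' @param landscape a [potts_model].
#' @param n_starts number of random starting sequences.
#' @param seed RNG seed (the survey is deterministic given the seed).
#' @param reference amino-acid string or index vector for endpoint
#'   distances (optional).
#' @param max_steps per-walk step cap.
#' @return data.frame: `endpoint` (amino-acid string), `basin` (count of
#'   starts reaching it), `score`, and `dist_ref` when a reference is
#'   given; sorted by decreasing basin.
#' @export
convergence_survey <- function(landscape, n_starts, seed = 1L,
                               reference = NULL, max_steps = 10000L) {
  stopifnot(n_starts >= 1L)
  set.seed(as.integer(seed))
  L <- landscape$L
  ab <- codon_alphabet()
  ends <- character(n_starts)
  endscore <- numeric(n_starts)
  for (k in seq_len(n_starts)) {
    start <- sample.int(20L, L, replace = TRUE)
    w <- adaptive_walk(landscape, start, moves = "single",
                       max_steps = max_steps)
    ends[k] <- paste0(ab$amino_acids[w$endpoint], collapse = "")
    endscore[k] <- if (length(w$scores)) w$scores[length(w$scores)] else
      w$start_score
  }
  tab <- table(ends)
  out <- data.frame(endpoint = names(tab), basin = as.integer(tab),
                    score = endscore[match(names(tab), ends)])
  if (!is.null(reference)) {
    refv <- as.integer(.aa_matrix(reference, L))
    out$dist_ref <- vapply(out$endpoint,
                           function(e) hamming(aa_index(e), refv), integer(1))
  }
  out <- out[order(-out$basin, out$endpoint), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Contact maps and PPV -------------------------------------------------------

#' Read / write a residue contact map
#'
#' Three-column TSV: `i`, `j` (1-based positions, i < j) and `distance`
#' (minimum heavy-atom distance in Angstrom).
#'
#' @param path TSV path.
#' @return data.frame of class `contact_map`.
#' @export
read_contact_map <- function(path) {
  tab <- utils::read.delim(path)
  stopifnot(all(c("i", "j", "distance") %in% names(tab)))
  contact_map(tab$i, tab$j, tab$distance)
}

#' @rdname read_contact_map
#' @param i,j 1-based residue positions (i < j enforced by swapping).
#' @param distance minimum heavy-atom distances (Angstrom, > 0).
#' @export
contact_map <- function(i, j, distance) {
  ii <- pmin(i, j); jj <- pmax(i, j)
  stopifnot(all(ii < jj), all(distance > 0))
  out <- data.frame(i = as.integer(ii), j = as.integer(jj),
                    distance = as.numeric(distance))
  class(out) <- c("contact_map", class(out))
  out
}

#' @rdname read_contact_map
#' @param map a `contact_map`.
#' @export
write_contact_map <- function(map, path) {
  utils::write.table(as.data.frame(unclass(map))[c("i", "j", "distance")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Positive predictive value of the interaction-score contact ranking
#'
#' Ranks long-range pairs (separation above the score object's
#' `min_separation`) by Frobenius score, takes the top `top_k`, and
#' reports the fraction whose structural distance is below each
#' threshold, together with the random-chance baseline (fraction of all
#' long-range pairs below the threshold).
#'
#' @param scores an [interaction_scores] object.
#' @param contacts a `contact_map`; pairs absent from the map are treated
#'   as non-contacts at any threshold.
#' @param thresholds distance thresholds in Angstrom (default 5 and 8).
#' @param top_k pairs evaluated (default `floor(L/2)`).
#' @return data.frame: `threshold`, `top_k`, `hits`, `ppv`, `baseline`.
#' @export
contact_ppv <- function(scores, contacts, thresholds = c(5, 8),
                        top_k = NULL) {
  L <- nrow(scores$F)
  if (is.null(top_k)) top_k <- floor(L / 2)
  ranked <- top_interactions(scores)
  if (nrow(ranked) < top_k)
    stop("fewer long-range pairs than top_k", call. = FALSE)
  top <- ranked[seq_len(top_k), ]
  dist_lookup <- matrix(Inf, L, L)
  dist_lookup[cbind(contacts$i, contacts$j)] <- contacts$distance
  sep <- abs(row(dist_lookup) - col(dist_lookup))
  lr <- upper.tri(dist_lookup) & sep > scores$min_separation
  n_lr <- sum(lr)
  top_d <- dist_lookup[cbind(top$i, top$j)]
  out <- do.call(rbind, lapply(thresholds, function(thr) {
    hits <- sum(top_d < thr)
    data.frame(threshold = thr, top_k = top_k, hits = hits,
               ppv = hits / top_k,
               baseline = sum(dist_lookup[lr] < thr) / n_lr)
  }))
  out
}

#' Export a walk as FASTA plus a score trace TSV
#' @param walk an [adaptive_walk].
#' @param fasta_path,tsv_path output paths.
#' @return invisibly, the two paths.
#' @export
write_walk <- function(walk, fasta_path, tsv_path) {
  ab <- codon_alphabet()
  seqs <- list(walk$start)
  cur <- walk$start
  for (k in seq_len(nrow(walk$steps))) {
    muts <- strsplit(walk$steps$mutation[k], "+", fixed = TRUE)[[1]]
    for (m in muts) {
      pos <- as.integer(gsub("[A-Z]", "", m))
      to <- substr(m, nchar(m), nchar(m))
      cur[pos] <- match(to, ab$amino_acids)
    }
    seqs[[k + 1L]] <- cur
  }
  aa <- vapply(seqs, function(s) paste0(ab$amino_acids[s], collapse = ""), "")
  x <- Biostrings::AAStringSet(aa)
  names(x) <- sprintf("step_%d", seq_along(aa) - 1L)
  Biostrings::writeXStringSet(x, fasta_path)
  utils::write.table(
    data.frame(step = seq_len(length(walk$scores)), score = walk$scores),
    tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta_path, tsv_path))
}
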