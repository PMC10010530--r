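# First/second-order codon marginals and the approximate recursive moment
# propagation: round-(r+1) marginals are expressed through the mutation
# kernel, the round-r marginals and the landscape's own marginals,
#   mu_i^(r+1)(c) = sum_c' g_i(c'->c) mu_i(c) mu_i^(r)(c')
#                   / sum_c'' g_i(c'->c'') mu_i(c''),
# with the analogous pairwise update under the product kernel g_i * g_j.
# The recursion preserves normalization exactly and is exact when the
# landscape factorizes over sites.

#' All unordered position pairs in canonical order
#' @param L residues.
#' @return integer matrix (choose(L,2) x 2), rows (i, j) with i < j in
#'   `combn` order.
#' @export
all_pairs <- function(L) {
  if (L < 2L) return(matrix(integer(0), ncol = 2L))
  t(utils::combn(L, 2L))
}

#' Construct a moment vector
#'
#' @param first L x 61 matrix of per-position codon marginals (rows sum
#'   to 1).
#' @param second `NULL`, or a 3721 x npairs matrix whose column p is the
#'   vectorized 61 x 61 block for pair `pairs[p, ]` (entry (c, d) at row
#'   `c + 61 * (d - 1)`).
#' @param pairs pair matrix matching `second` (default [all_pairs]).
#' @return object of class `moment_vector`.
#' @export
moment_vector <- function(first, second = NULL, pairs = NULL) {
  stopifnot(is.matrix(first), ncol(first) == 61L)
  if (!is.null(second)) {
    if (is.null(pairs)) pairs <- all_pairs(nrow(first))
    stopifnot(nrow(second) == 3721L, ncol(second) == nrow(pairs))
  }
  structure(list(first = first, second = second, pairs = pairs),
            class = "moment_vector")
}

#' @export
print.moment_vector <- function(x, ...) {
  cat(sprintf("moment_vector: L = %d%s\n", nrow(x$first),
              if (is.null(x$second)) ", first-order only" else
                sprintf(", %d pair blocks", ncol(x$second))))
  invisible(x)
}

#' Empirical codon frequencies of a round sample
#'
#' Indicator averages over the sample: `f_i(c)` is the fraction of
#' sequences carrying codon c at position i, and `f_ij(c, d)` the fraction
#' carrying the codon pair, for every unordered pair i < j.
#'
#' @param sample a [round_sample].
#' @param second compute pairwise frequencies too (default TRUE).
#' @return a [moment_vector] with attributes `n` (sample size) and
#'   `round`.
#' @export
empirical_frequencies <- function(sample, second = TRUE) {
  stopifnot(inherits(sample, "round_sample"))
  m <- sample$seqs
  n <- nrow(m); L <- ncol(m)
  first <- t(apply(m, 2L, tabulate, nbins = 61L)) / n
  sec <- NULL; pairs <- NULL
  if (second && L >= 2L) {
    pairs <- all_pairs(L)
    sec <- matrix(0, 3721L, nrow(pairs))
    for (p in seq_len(nrow(pairs))) {
      code <- m[, pairs[p, 1]] + 61L * (m[, pairs[p, 2]] - 1L)
      sec[, p] <- tabulate(code, nbins = 3721L) / n
    }
  }
  out <- moment_vector(first, sec, pairs)
  attr(out, "n") <- n
  attr(out, "round") <- sample$round
  out
}

#' Round-0 moments: a point mass at the wild-type
#'
#' At the start of the experiment only wild-type copies are present, so
#' every first-order block is an indicator at the wild-type codon and
#' every pair block an indicator at the wild-type codon pair.
#'
#' @param wildtype integer codon-index vector.
#' @param second include pair blocks (default TRUE).
#' @return a [moment_vector] of exact zeros and ones.
#' @export
init_moments <- function(wildtype, second = TRUE) {
  wildtype <- as.integer(wildtype)
  L <- length(wildtype)
  first <- matrix(0, L, 61L)
  first[cbind(seq_len(L), wildtype)] <- 1
  sec <- NULL; pairs <- NULL
  if (second && L >= 2L) {
    pairs <- all_pairs(L)
    sec <- matrix(0, 3721L, nrow(pairs))
    code <- wildtype[pairs[, 1]] + 61L * (wildtype[pairs[, 2]] - 1L)
    sec[cbind(code, seq_len(nrow(pairs)))] <- 1
  }
  moment_vector(first, sec, pairs)
}

# batched block linear algebra: blocks are 3721 x npairs matrices ---------

# K %*% M for every block
.blk_left <- function(K, B) {
  np <- ncol(B)
  dim(B) <- c(61L, 61L * np)
  R <- K %*% B
  dim(R) <- c(3721L, np)
  R
}

# M %*% K for every block
.blk_right <- function(K, B) {
  np <- ncol(B)
  A <- aperm(array(B, c(61L, 61L, np)), c(2L, 1L, 3L))
  dim(A) <- c(61L, 61L * np)
  R <- t(K) %*% A
  R <- aperm(array(R, c(61L, 61L, np)), c(2L, 1L, 3L))
  dim(R) <- c(3721L, np)
  R
}

# K A K^T for every block
.blk_sandwich <- function(K, B) .blk_right(t(K), .blk_left(K, B))

#' One step of the recursive moment propagation
#'
#' Implements the printed recursion exactly: the first-order update above
#' and the pairwise update with the product kernel over the two positions
#' (no higher-order corrections). A zero denominator (landscape mass
#' unreachable from a populated codon) is a configuration error and
#' raises, naming the position.
#'
#' @param mu_landscape [moment_vector] of landscape marginals (the fitness
#'   distribution's own marginals).
#' @param mu_round [moment_vector] of the current round's marginals.
#' @param model a `mutation_model`.
#' @return the next round's [moment_vector]; block sums are asserted to be
#'   1 within 1e-9 after every call.
#' @export
propagate_moments <- function(mu_landscape, mu_round, model) {
  M <- mu_landscape$first
  P <- mu_round$first
  L <- nrow(M)
  shared <- is.null(model$per_position)
  K <- model$kernel
  if (shared) {
    D <- M %*% t(K)                       # D[i, c'] = sum_c g(c'->c) M[i, c]
    bad <- D <= 0 & P > 0
    if (any(bad))
      stop("zero denominator in moment propagation at position ",
           which(rowSums(bad) > 0)[1], call. = FALSE)
    W <- ifelse(P > 0, P / D, 0)
    first <- M * (W %*% K)
  } else {
    first <- matrix(0, L, 61L)
    for (i in seq_len(L)) {
      Ki <- kernel_for(model, i)
      d <- as.vector(Ki %*% M[i, ])
      if (any(d <= 0 & P[i, ] > 0))
        stop("zero denominator in moment propagation at position ", i,
             call. = FALSE)
      w <- ifelse(P[i, ] > 0, P[i, ] / d, 0)
      first[i, ] <- M[i, ] * as.vector(t(Ki) %*% w)
    }
  }
  stopifnot(all(abs(rowSums(first) - 1) < 1e-9))
  second <- NULL
  if (!is.null(mu_landscape$second)) {
    stopifnot(!is.null(mu_round$second))
    if (!shared)
      stop("per-position kernels not supported in pairwise propagation",
           call. = FALSE)
    Msec <- mu_landscape$second
    Psec <- mu_round$second
    D2 <- .blk_sandwich(K, Msec)
    bad <- D2 <= 0 & Psec > 0
    if (any(bad))
      stop("zero denominator in pairwise moment propagation (pair ",
           which(colSums(bad) > 0)[1], ")", call. = FALSE)
    W2 <- ifelse(Psec > 0, Psec / D2, 0)
    second <- Msec * .blk_sandwich(t(K), W2)
    stopifnot(all(abs(colSums(second) - 1) < 1e-9))
  }
  moment_vector(first, second, mu_landscape$pairs)
}

#' Marginal consistency check of a moment vector
#'
#' Verifies that every pair block marginalizes to the corresponding
#' first-order blocks.
#'
#' @param mv a [moment_vector] with pair blocks.
#' @param tol tolerance.
#' @return largest absolute marginalization discrepancy, invisibly;
#'   errors if above `tol`.
#' @export
check_local_consistency <- function(mv, tol = 1e-8) {
  stopifnot(!is.null(mv$second))
  worst <- 0
  for (p in seq_len(ncol(mv$second))) {
    blk <- matrix(mv$second[, p], 61L, 61L)
    i <- mv$pairs[p, 1]; j <- mv$pairs[p, 2]
    worst <- max(worst,
                 max(abs(rowSums(blk) - mv$first[i, ])),
                 max(abs(colSums(blk) - mv$first[j, ])))
  }
  if (worst > tol)
    stop("moment vector is not locally consistent (max discrepancy ",
         signif(worst, 3), ")", call. = FALSE)
  invisible(worst)
}

#' Export first-order moments as a TSV table
#' @param mv a [moment_vector].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_first_order_tsv <- function(mv, path) {
  ab <- codon_alphabet()
  tab <- as.data.frame(mv$first)
  names(tab) <- ab$codons
  tab <- cbind(position = seq_len(nrow(tab)), tab)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
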