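# Error-prone-PCR-style mutation model: a 4x4 nucleotide substitution bias
# scaled to a target per-gene mutation load, lifted to per-position 61x61
# codon transition kernels g_i over the sense codons.

#' Read a nucleotide substitution-bias table
#'
#' The table is TSV with a header row and a `from` column, both over the
#' bases A, C, G, T; entry (b, b') is the relative propensity of the
#' substitution b -> b' (the diagonal is ignored). Only the relative
#' magnitudes matter; [build_mutation_model] applies one global scale.
#'
#' @param path TSV path. The default is the packaged synthetic
#'   representative Taq-style error-prone PCR spectrum
#'   (`epcr_bias_synthetic.tsv`): transition-dominated and A/T-biased, as
#'   is typical for MnCl2-doped Taq mutagenesis. It is a constructed
#'   stand-in, not measured data; substitute your own table for real
#'   experiments.
#' @return a 4x4 numeric matrix with dimnames A,C,G,T (class
#'   `nucleotide_bias`), diagonal set to 0.
#' @export
read_bias_tsv <- function(path = system.file("extdata", "epcr_bias_synthetic.tsv",
                                             package = "evoscape")) {
  tab <- utils::read.delim(path, check.names = FALSE)
  rownames(tab) <- tab[[1]]
  m <- as.matrix(tab[, -1, drop = FALSE])
  bases <- c("A", "C", "G", "T")
  if (!all(bases %in% rownames(m)) || !all(bases %in% colnames(m)))
    stop("bias table must have rows and columns A, C, G, T", call. = FALSE)
  m <- m[bases, bases]
  diag(m) <- 0
  if (any(m < 0) || all(m == 0))
    stop("bias entries must be non-negative with at least one positive",
         call. = FALSE)
  structure(m, class = c("nucleotide_bias", class(m)))
}

#' Build per-position codon mutation kernels from a nucleotide bias
#'
#' The 4x4 bias is normalized by one global scale (preserving the relative
#' spectrum) so that, for a base drawn uniformly from A,C,G,T, the expected
#' number of substitutions over the gene's `3*L` bases equals
#' `target_load`. The per-codon kernel is the 3-fold product of independent
#' per-base transitions; columns landing on stop codons are removed and
#' rows renormalized over the 61 sense codons (transitions into stops are
#' treated as lethal).
#'
#' @param bias 4x4 matrix from [read_bias_tsv].
#' @param target_load expected DNA substitutions per gene per round
#'   (the framework default mirrors an average of 4).
#' @param L number of residues (codons) in the gene.
#' @param per_position optional named list `position -> 61x61 kernel`
#'   overriding the shared kernel at specific positions.
#' @return object of class `mutation_model`: fields `kernel` (shared 61x61
#'   row-stochastic matrix), `per_base` (4x4 transition matrix including
#'   diagonal), `scale`, `bias_norm`, `target_load`, `L`, `per_position`.
#' @examples
#' m <- build_mutation_model(read_bias_tsv(), target_load = 4, L = 186)
#' range(rowSums(m$kernel))  # all 1
#' @export
build_mutation_model <- function(bias, target_load, L, per_position = NULL) {
  stopifnot(target_load >= 0, L >= 1)
  b <- unclass(bias)
  diag(b) <- 0
  bias_norm <- b / mean(rowSums(b))       # mean per-base rate = 1
  s <- target_load / (3 * L)              # per-base substitution probability scale
  per_base <- s * bias_norm
  stay <- 1 - rowSums(per_base)
  if (any(stay <= 0))
    stop("target_load too large: per-base substitution probability >= 1",
         call. = FALSE)
  diag(per_base) <- diag(per_base) + stay
  kernel <- .codon_kernel(per_base)
  if (!is.null(per_position)) {
    pos <- as.integer(names(per_position))
    stopifnot(all(pos >= 1L & pos <= L))
    for (k in per_position) stopifnot(is.matrix(k), all(dim(k) == c(61L, 61L)))
  }
  structure(list(kernel = kernel, per_base = per_base, scale = s,
                 bias_norm = bias_norm, target_load = target_load,
                 L = as.integer(L), per_position = per_position),
            class = "mutation_model")
}

# 61x61 sense-codon kernel from a full 4x4 per-base transition matrix
.codon_kernel <- function(per_base) {
  ab <- codon_alphabet()
  k64 <- per_base %x% per_base %x% per_base  # lexicographic base order matches codons
  bases <- c("A", "C", "G", "T")
  all64 <- sort(apply(expand.grid(bases, bases, bases, stringsAsFactors = FALSE)[, 3:1],
                      1, paste0, collapse = ""))
  sense <- match(ab$codons, all64)
  k <- k64[sense, sense]
  k / rowSums(k)
}

#' @export
print.mutation_model <- function(x, ...) {
  cat(sprintf("mutation_model: L = %d residues, target load %.3g DNA substitutions/gene/round\n",
              x$L, x$target_load))
  cat(sprintf("  per-base scale %.3g; shared 61x61 codon kernel%s\n", x$scale,
              if (is.null(x$per_position)) "" else
                sprintf(" with %d per-position overrides", length(x$per_position))))
  invisible(x)
}

#' Kernel acting at one residue position
#' @param model a `mutation_model`.
#' @param i 1-based residue position.
#' @return 61x61 row-stochastic matrix g_i.
#' @export
kernel_for <- function(model, i) {
  if (!is.null(model$per_position)) {
    k <- model$per_position[[as.character(i)]]
    if (!is.null(k)) return(k)
  }
  model$kernel
}

#' Probability that one codon sequence mutates into another
#'
#' Mutation acts independently per position, so the sequence-level
#' probability is the product of per-position kernel entries.
#'
#' @param model a `mutation_model`.
#' @param x,y integer codon-index vectors of equal length.
#' @return `prod_i g_i(x_i -> y_i)`.
#' @export
sequence_mutation_prob <- function(model, x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  p <- 1
  for (i in seq_along(x)) p <- p * kernel_for(model, i)[x[i], y[i]]
  p
}

#' Analytic expected DNA mutation load per gene per round
#'
#' Expectation of the number of nucleotide substitutions over the gene's
#' `3*L` bases under the per-base model (before stop-codon
#' renormalization), for uniformly composed DNA; by construction of
#' [build_mutation_model] this equals the target load.
#'
#' @param model a `mutation_model`.
#' @return expected substitutions per gene per round.
#' @export
expected_load <- function(model) {
  off <- model$per_base
  diag(off) <- 0
  3 * model$L * mean(rowSums(off))
}
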