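# Containers for per-round population samples and whole trajectories.
# Sequences are stored as integer codon-index matrices (rows = individuals,
# columns = residue positions); positions are 0-based nowhere and 1-based
# everywhere in user-facing output.

#' A sample of sequences from one round of evolution
#'
#' @param seqs integer matrix (n x L) of codon indices, or a character
#'   vector of in-frame DNA strings of equal length.
#' @param round non-negative integer generation index (round 0 is the
#'   unmutagenized starting population).
#' @return An object of class `round_sample` with fields `round` and
#'   `seqs` (integer matrix).
#' @export
round_sample <- function(seqs, round) {
  if (is.character(seqs)) {
    rows <- lapply(seqs, dna_to_codons)
    L <- unique(lengths(rows))
    if (length(L) != 1L) stop("sequences differ in length", call. = FALSE)
    seqs <- do.call(rbind, rows)
  }
  stopifnot(is.matrix(seqs), nrow(seqs) >= 1L)
  storage.mode(seqs) <- "integer"
  if (any(seqs < 1L | seqs > 61L))
    stop("invalid sequence: codon index out of range", call. = FALSE)
  round <- as.integer(round)
  stopifnot(length(round) == 1L, round >= 0L)
  structure(list(round = round, seqs = seqs), class = "round_sample")
}

#' @export
print.round_sample <- function(x, ...) {
  cat(sprintf("round_sample: round %d, %d sequences of length %d residues\n",
              x$round, nrow(x$seqs), ncol(x$seqs)))
  invisible(x)
}

#' A multi-round directed-evolution dataset
#'
#' Bundles the wild-type coding sequence with the population samples from
#' the sequenced rounds. All samples must share the wild-type's residue
#' length; round indices must be strictly increasing.
#'
#' @param wildtype integer codon-index vector or an in-frame DNA string.
#' @param rounds list of [round_sample] objects.
#' @return An object of class `trajectory_dataset` with fields `wildtype`,
#'   `rounds` (list named by round index) and `sequenced_rounds`.
#' @export
trajectory_dataset <- function(wildtype, rounds) {
  if (is.character(wildtype)) wildtype <- dna_to_codons(wildtype)
  stopifnot(length(rounds) >= 1L)
  ok <- vapply(rounds, inherits, logical(1), "round_sample")
  if (!all(ok)) stop("rounds must be a list of round_sample objects", call. = FALSE)
  r <- vapply(rounds, `[[`, integer(1), "round")
  if (any(duplicated(r)) || is.unsorted(r, strictly = TRUE))
    rounds <- rounds[order(r)]
  r <- sort(r)
  if (any(duplicated(r)))
    stop("duplicate round indices", call. = FALSE)
  L <- length(wildtype)
  Ls <- vapply(rounds, function(s) ncol(s$seqs), integer(1))
  if (any(Ls != L))
    stop("sample length differs from wild-type length", call. = FALSE)
  names(rounds) <- as.character(r)
  structure(list(wildtype = as.integer(wildtype), rounds = rounds,
                 sequenced_rounds = r),
            class = "trajectory_dataset")
}

#' @export
print.trajectory_dataset <- function(x, ...) {
  n <- vapply(x$rounds, function(s) nrow(s$seqs), integer(1))
  cat(sprintf("trajectory_dataset: L = %d residues, sequenced rounds: %s\n",
              length(x$wildtype),
              paste(sprintf("%s (n=%d)", names(x$rounds), n), collapse = ", ")))
  invisible(x)
}

# FASTA I/O ----------------------------------------------------------------

#' Read one round's population sample from a DNA FASTA file
#'
#' Records must be in-frame coding DNA of identical length. Records whose
#' length differs from the (majority) frame, that contain ambiguity codes,
#' or that contain an internal stop codon are rejected; the number of
#' rejections is attached as attribute `"rejected"` and reported via a
#' message.
#'
#' @param path FASTA file path.
#' @param round generation index to attach to the sample.
#' @return a [round_sample]; attribute `rejected` counts dropped records.
#' @export
read_round_fasta <- function(path, round) {
  dna <- Biostrings::readDNAStringSet(path)
  if (length(dna) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  chars <- as.character(dna)
  widths <- nchar(chars)
  expect <- as.integer(names(sort(table(widths[widths %% 3L == 0L]),
                                  decreasing = TRUE))[1])
  if (is.na(expect)) stop("no in-frame records in ", path, call. = FALSE)
  rows <- vector("list", length(chars))
  keep <- logical(length(chars))
  for (k in seq_along(chars)) {
    if (widths[k] != expect) next
    row <- tryCatch(dna_to_codons(chars[k]), error = function(e) NULL)
    if (!is.null(row)) { rows[[k]] <- row; keep[k] <- TRUE }
  }
  n_rej <- sum(!keep)
  if (!any(keep)) stop("no valid records in ", path, call. = FALSE)
  if (n_rej > 0L)
    message(sprintf("read_round_fasta: rejected %d of %d records (length mismatch, ambiguity or stop codon)",
                    n_rej, length(chars)))
  out <- round_sample(do.call(rbind, rows[keep]), round)
  attr(out, "rejected") <- n_rej
  out
}

#' Write a round sample to a DNA FASTA file
#'
#' Record names are `r<round>_<index>`; [read_round_fasta] inverts this
#' exactly (round-trip identity on the codon matrix).
#'
#' @param sample a [round_sample].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_round_fasta <- function(sample, path) {
  stopifnot(inherits(sample, "round_sample"))
  dna <- apply(sample$seqs, 1L, codons_to_dna)
  x <- Biostrings::DNAStringSet(dna)
  names(x) <- sprintf("r%d_%d", sample$round, seq_along(dna))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a wild-type coding sequence from FASTA
#' @param path FASTA path; the first record is used.
#' @return integer codon-index vector.
#' @export
read_wildtype_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  if (length(dna) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  dna_to_codons(as.character(dna[[1]]))
}

# Population statistics -----------------------------------------------------

#' Per-round population summary statistics
#'
#' For each sequenced round, computes the mean amino-acid Hamming distance
#' to the wild-type and the mean pairwise amino-acid Hamming distance
#' within the population. The pairwise mean is computed exactly over all
#' unordered pairs using per-position amino-acid counts (the sum over
#' pairs of per-position mismatches), so no pair subsampling is needed at
#' any population size. Codon-level distances are available via `level`.
#'
#' @param dataset a [trajectory_dataset].
#' @param level `"aa"` (default, matches how substitutions are usually
#'   reported) or `"codon"`.
#' @return data.frame with columns `round`, `n`, `mean_dist_wt`,
#'   `mean_pairwise`, `single_sequence` (flag: pairwise mean degenerate).
#' @export
population_stats <- function(dataset, level = c("aa", "codon")) {
  stopifnot(inherits(dataset, "trajectory_dataset"))
  level <- match.arg(level)
  ab <- codon_alphabet()
  wt <- dataset$wildtype
  if (level == "aa") wt <- ab$ac_map[wt]
  nsym <- if (level == "aa") 20L else 61L
  res <- lapply(dataset$rounds, function(s) {
    m <- s$seqs
    if (nrow(m) < 1L) stop("empty round", call. = FALSE)
    if (level == "aa") m <- matrix(ab$ac_map[m], nrow = nrow(m))
    n <- nrow(m)
    d_wt <- mean(colSums(t(m) != wt))
    if (n == 1L) {
      pw <- 0; flag <- TRUE
    } else {
      npairs <- n * (n - 1) / 2
      same <- 0
      for (j in seq_len(ncol(m))) {
        cnt <- tabulate(m[, j], nbins = nsym)
        same <- same + sum(cnt * (cnt - 1) / 2)
      }
      pw <- (ncol(m) * npairs - same) / npairs
      flag <- FALSE
    }
    data.frame(round = s$round, n = n, mean_dist_wt = d_wt,
               mean_pairwise = pw, single_sequence = flag)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
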