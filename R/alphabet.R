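#' The sense-codon alphabet
#'
#' The state space of the evolutionary Markov chain is the set of codon
#' sequences over the 61 sense codons (the 64 triplets over \{A,C,G,T\}
#' minus the three stop codons). This function returns the canonical
#' alphabet used everywhere in the package: codons are ordered
#' lexicographically over \{A,C,G,T\}^3 with stops removed, and that
#' ordering is the row/column index of every codon-level matrix the
#' package produces or consumes.
#'
#' @return An object of class `codon_alphabet`: a list with
#'   \describe{
#'     \item{codons}{character(61), the sense codons in canonical order.}
#'     \item{amino_acids}{character(20), one-letter amino acids in the
#'       order they are indexed in all amino-acid-level matrices.}
#'     \item{ac_map}{integer(61), amino-acid index of each codon
#'       (the map `AC(.)` from codons to residues).}
#'     \item{multiplicity}{integer(20), number of sense codons encoding
#'       each amino acid (sums to 61).}
#'   }
#' @examples
#' ab <- codon_alphabet()
#' length(ab$codons)            # 61
#' ab$amino_acids[ab$ac_map[1]] # amino acid encoded by "AAA"
#' @export
codon_alphabet <- function() {
  if (is.null(.pkg_env$alphabet)) .pkg_env$alphabet <- .build_alphabet()
  .pkg_env$alphabet
}

.pkg_env <- new.env(parent = emptyenv())

.build_alphabet <- function() {
  bases <- c("A", "C", "G", "T")
  all64 <- sort(apply(expand.grid(bases, bases, bases, stringsAsFactors = FALSE)[, 3:1],
                      1, paste0, collapse = ""))
  gc_tab <- Biostrings::GENETIC_CODE
  aa64 <- unname(gc_tab[all64])
  sense <- all64[aa64 != "*"]
  aa_sense <- aa64[aa64 != "*"]
  amino_acids <- sort(unique(aa_sense))
  stopifnot(length(sense) == 61L, length(amino_acids) == 20L)
  ac_map <- match(aa_sense, amino_acids)
  multiplicity <- as.integer(table(factor(aa_sense, levels = amino_acids)))
  structure(list(codons = sense,
                 amino_acids = amino_acids,
                 ac_map = as.integer(ac_map),
                 multiplicity = multiplicity),
            class = "codon_alphabet")
}

#' @export
print.codon_alphabet <- function(x, ...) {
  cat("Sense-codon alphabet: 61 codons -> 20 amino acids\n")
  cat("codon order: lexicographic over {A,C,G,T}^3, stops removed\n")
  invisible(x)
}

# codon index <-> string helpers ------------------------------------------

#' Convert codon strings to canonical codon indices
#'
#' @param codons character vector of 3-letter DNA codons.
#' @return integer vector of indices into `codon_alphabet()$codons`.
#'   Stop codons or unknown triplets raise an invalid-sequence error.
#' @keywords internal
codon_index <- function(codons) {
  ab <- codon_alphabet()
  idx <- match(codons, ab$codons)
  if (anyNA(idx)) {
    bad <- unique(codons[is.na(idx)])
    stop("invalid sequence: non-sense or unknown codon(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  idx
}

#' Encode an in-frame DNA string as a codon-index sequence
#'
#' @param dna a single DNA string whose length is a multiple of 3.
#' @return integer vector of codon indices (class-free; a "codon sequence").
#' @examples
#' dna_to_codons("ATGAAA")
#' @export
dna_to_codons <- function(dna) {
  stopifnot(is.character(dna), length(dna) == 1L)
  dna <- toupper(dna)
  n <- nchar(dna)
  if (n == 0L || n %% 3L != 0L)
    stop("invalid sequence: length ", n, " is not a positive multiple of 3",
         call. = FALSE)
  if (grepl("[^ACGT]", dna))
    stop("invalid sequence: ambiguity codes or non-ACGT characters present",
         call. = FALSE)
  starts <- seq(1L, n, by = 3L)
  codon_index(substring(dna, starts, starts + 2L))
}

#' Decode codon indices back to a DNA string
#' @param codons integer vector of codon indices.
#' @return a single DNA string.
#' @export
codons_to_dna <- function(codons) {
  ab <- codon_alphabet()
  paste0(ab$codons[codons], collapse = "")
}

#' Translate a codon sequence to an amino-acid string
#'
#' Applies the codon-to-residue map `AC(.)` position by position. Input is
#' either an integer codon-index vector (canonical internal form) or an
#' in-frame DNA string.
#'
#' @param seq integer codon indices or a single DNA string.
#' @return a single amino-acid string of the same residue length.
#' @examples
#' translate_codons("ATGAAA")  # "MK"
#' @export
translate_codons <- function(seq) {
  if (is.character(seq)) seq <- dna_to_codons(seq)
  ab <- codon_alphabet()
  if (any(seq < 1L | seq > 61L))
    stop("invalid sequence: codon index out of range", call. = FALSE)
  paste0(ab$amino_acids[ab$ac_map[seq]], collapse = "")
}

#' Amino-acid indices of a codon sequence
#' @param seq integer codon indices.
#' @return integer vector of amino-acid indices (1..20).
#' @keywords internal
aa_of <- function(seq) {
  ab <- codon_alphabet()
  ab$ac_map[seq]
}

#' Convert an amino-acid string to indices
#' @param aa a single amino-acid string.
#' @return integer vector of indices into `codon_alphabet()$amino_acids`.
#' @export
aa_index <- function(aa) {
  ab <- codon_alphabet()
  idx <- match(strsplit(toupper(aa), "")[[1]], ab$amino_acids)
  if (anyNA(idx))
    stop("invalid amino-acid string", call. = FALSE)
  idx
}

#' Hamming distance between two equal-length index vectors
#' @param x,y integer vectors of equal length.
#' @return integer count of differing positions.
#' @export
hamming <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  sum(x != y)
}
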