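#' The 20-letter amino-acid alphabet
#'
#' The canonical one-letter codes in alphabetical order. Every matrix in the
#' package (PWMs, count matrices, background vectors, substitution tables)
#' indexes its residue dimension in this fixed order.
#'
#' @return Character vector of length 20 (`"A"`, `"C"`, ..., `"Y"`).
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# fast lookup table: residue character -> 1..20, NA for anything else
.aa_index <- local({
  idx <- rep(NA_integer_, 256)
  ab <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  idx[utf8ToInt(paste(ab, collapse = "")) ] <- seq_along(ab)
  idx
})

#' Encode peptides as a residue-index matrix
#'
#' Converts `n` equal-length peptides into an `n x L` integer matrix of
#' 1-based indices into [aa_alphabet()]. Used internally by the EM engine
#' and the scoring functions.
#'
#' @param peptides Character vector of equal-length peptides.
#' @return Integer matrix, one row per peptide.
#' @keywords internal
encode_peptides <- function(peptides) {
  if (length(peptides) == 0L) stop("no peptides to encode")
  L <- unique(nchar(peptides))
  if (length(L) != 1L) stop("peptides must all have the same length")
  m <- matrix(.aa_index[utf8ToInt(paste(peptides, collapse = ""))],
              ncol = L, byrow = TRUE)
  if (anyNA(m)) stop("peptides contain non-canonical residues")
  m
}

#' Check peptides for canonical residues
#'
#' @param peptides Character vector.
#' @return Logical vector: TRUE where every residue is one of the 20
#'   canonical amino acids.
#' @export
is_canonical_peptide <- function(peptides) {
  grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", peptides)
}
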