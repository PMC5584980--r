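#' Position weight matrices
#'
#' A PWM is an `L x 20` matrix of per-position amino-acid probabilities:
#' row `i` holds the distribution over the 20 canonical residues at peptide
#' position `i` (P1..PL). Rows are named `P1..PL`, columns follow
#' [aa_alphabet()]. Each row must sum to 1.
#'
#' @param m Numeric `L x 20` matrix (rows positions, columns residues).
#' @return An object of class `pwm`.
#' @export
#' @examples
#' uniform_pwm(9)
pwm <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) != 20L) stop("a PWM needs 20 residue columns, got ", ncol(m))
  if (any(m < 0)) stop("PWM entries must be non-negative")
  rs <- rowSums(m)
  if (any(abs(rs - 1) > 1e-9)) {
    stop("PWM rows must each sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  }
  dimnames(m) <- list(paste0("P", seq_len(nrow(m))), aa_alphabet())
  class(m) <- c("pwm", "matrix")
  m
}

#' @rdname pwm
#' @param L Peptide length.
#' @export
uniform_pwm <- function(L) {
  pwm(matrix(1 / 20, nrow = L, ncol = 20))
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM, length", nrow(x), "\n")
  print(round(unclass(x), 3), ...)
  invisible(x)
}

#' Is an object a valid PWM?
#'
#' @param x Object to test.
#' @return TRUE/FALSE.
#' @export
is_pwm <- function(x) {
  is.matrix(x) && ncol(x) == 20L && all(x >= 0) &&
    all(abs(rowSums(x) - 1) <= 1e-9)
}

#' Per-position residue count matrix of a peptide set
#'
#' Counts residue occurrences at each position of `n` equal-length
#' peptides; positions are rows as in [pwm()]. Each row sums to `n`.
#'
#' @param peptides Character vector of equal-length peptides.
#' @param weights Optional per-peptide weights (defaults to 1); fractional
#'   weights arise when counting by mixture responsibilities.
#' @return An `L x 20` matrix with attribute `n` = total weight.
#' @export
count_matrix <- function(peptides, weights = NULL) {
  idx <- encode_peptides(peptides)
  n <- nrow(idx)
  L <- ncol(idx)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("weights must match the number of peptides")
  cm <- matrix(0, nrow = L, ncol = 20,
               dimnames = list(paste0("P", seq_len(L)), aa_alphabet()))
  for (i in seq_len(L)) {
    s <- rowsum(weights, group = idx[, i])
    cm[i, as.integer(rownames(s))] <- s[, 1]
  }
  attr(cm, "n") <- sum(weights)
  cm
}

#' Empirical (unsmoothed) PWM of a peptide set
#'
#' @inheritParams count_matrix
#' @return A [pwm()] of the per-position relative frequencies.
#' @export
frequency_pwm <- function(peptides, weights = NULL) {
  cm <- count_matrix(peptides, weights)
  f <- cm / rowSums(cm)
  attr(f, "n") <- NULL
  pwm(f)
}

#' Reference-style PWM with a flat +1 count
#'
#' Builds a PWM from per-position residue frequencies with a random count
#' of 1 added for each amino acid at each position, i.e.
#' `(count + 1) / (n + 20)`. This is the construction used for reference
#' motif compendia derived from curated ligand databases and for the final
#' pooled per-allele motifs.
#'
#' @param peptides Character vector of equal-length peptides.
#' @return A [pwm()].
#' @export
#' @examples
#' build_reference_pwm(c("AAAAAAAAA"))[1, ]  # A: 2/21, rest 1/21
build_reference_pwm <- function(peptides) {
  if (length(peptides) < 1L) stop("need at least one peptide")
  if (length(unique(nchar(peptides))) != 1L) {
    stop("peptides must all have the same length")
  }
  cm <- count_matrix(peptides)
  n <- attr(cm, "n")
  pwm((cm + 1) / (n + 20))
}

#' Sample peptides from a PWM
#'
#' Draws peptides position-independently from a PWM, optionally applying a
#' residue-level detection bias (e.g. cysteine depletion in MS data): the
#' per-position probabilities are multiplied by `bias` and renormalized
#' before sampling, so the bias lives in the data, not in the motif.
#'
#' @param p A [pwm()].
#' @param n Number of peptides to draw.
#' @param bias Optional length-20 multiplicative bias over residues.
#' @return Character vector of `n` peptides.
#' @export
sample_from_pwm <- function(p, n, bias = NULL) {
  stopifnot(is_pwm(p), n >= 0)
  if (n == 0L) return(character(0))
  m <- unclass(p)
  if (!is.null(bias)) {
    stopifnot(length(bias) == 20L, all(bias >= 0))
    m <- sweep(m, 2, bias, `*`)
    m <- m / rowSums(m)
  }
  L <- nrow(m)
  ab <- aa_alphabet()
  cols <- lapply(seq_len(L), function(i) {
    ab[sample.int(20L, n, replace = TRUE, prob = m[i, ])]
  })
  do.call(paste0, cols)
}
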