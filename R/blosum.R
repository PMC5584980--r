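# BLOSUM62-based substitution pseudocounts.
#
# The pseudocount scheme needs the conditional substitution probabilities
# rho[B, A] = P(A | B) implied by the BLOSUM62 joint residue-pair
# frequencies. The published integer BLOSUM62 matrix stores half-bit
# log-odds s_ij = 2 * log2(q_ij / (p_i * p_j)); the joint table q (and its
# marginals p) is recovered here by solving q_ij = p_i * p_j * 2^(s_ij/2)
# under the marginal-consistency condition rowSums(q) = p, which reduces to
# the linear system odds %*% p = const (p proportional to solve(odds, 1)).
# The resulting rho rows sum to 1 by construction.

.blosum_cache <- new.env(parent = emptyenv())

#' BLOSUM62 conditional substitution matrix
#'
#' Returns the 20 x 20 matrix `rho` with `rho[B, A] = P(A | B)` derived
#' from the BLOSUM62 substitution matrix (see the package source for the
#' reconstruction of the joint frequency table from the published half-bit
#' log-odds). Rows and columns follow [aa_alphabet()]; each row sums to 1.
#'
#' @return Numeric 20 x 20 matrix.
#' @export
blosum62_conditional <- function() {
  if (!is.null(.blosum_cache$rho)) return(.blosum_cache$rho)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  s <- get("BLOSUM62", envir = environment())[aa_alphabet(), aa_alphabet()]
  odds <- 2^(s / 2)
  # marginal consistency rowSums(q) == p requires odds %*% p to be constant
  # across residues, i.e. p proportional to solve(odds, 1)
  p <- solve(odds, rep(1, 20))
  if (any(p <= 0)) stop("implied background frequencies are not positive")
  p <- p / sum(p)
  q <- outer(p, p) * odds
  q <- q / sum(q)
  rho <- q / rowSums(q)
  dimnames(rho) <- list(aa_alphabet(), aa_alphabet())
  .blosum_cache$rho <- rho
  .blosum_cache$marginals <- stats::setNames(rowSums(q), aa_alphabet())
  rho
}

#' Pseudocount parameters for per-allele PWMs
#'
#' @param beta Pseudocount weight (default 200).
#' @param rho Conditional substitution matrix; defaults to
#'   [blosum62_conditional()].
#' @return A list of class `pseudocount_params`.
#' @export
pseudocount_params <- function(beta = 200, rho = blosum62_conditional()) {
  stopifnot(beta > 0, is.matrix(rho), nrow(rho) == 20L, ncol(rho) == 20L)
  if (any(abs(rowSums(rho) - 1) > 1e-9)) stop("rho rows must sum to 1")
  structure(list(beta = beta, rho = rho), class = "pseudocount_params")
}

#' Approximate human proteome amino-acid frequencies
#'
#' A standard composition vector for human (SwissProt-like) protein
#' sequences, used as the default residue distribution of the synthetic
#' proteome generator and as a proteome-level background. Indexed by
#' [aa_alphabet()]; sums to 1.
#'
#' @return Named numeric vector of length 20.
#' @export
human_aa_frequencies <- function() {
  f <- c(A = 0.0702, C = 0.0230, D = 0.0473, E = 0.0710, F = 0.0365,
         G = 0.0657, H = 0.0263, I = 0.0433, K = 0.0573, L = 0.0996,
         M = 0.0213, N = 0.0359, P = 0.0631, Q = 0.0477, R = 0.0564,
         S = 0.0833, T = 0.0536, V = 0.0597, W = 0.0122, Y = 0.0266)
  f / sum(f)
}
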