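#' Similarity configuration for motif comparison
#'
#' @param T Distance threshold on the squared Euclidean PWM distance used
#'   to call two motifs "the same" (default 0.078). The boundary counts as
#'   similar (`<=`).
#' @param metric `"euclidean"` (distance, smaller = more similar) or
#'   `"blic"` (score, larger = more similar).
#' @param blic_alpha Dirichlet hyper-parameters for the BLiC score
#'   (default: all 1).
#' @param background Length-20 background residue frequencies used by the
#'   BLiC score (default [human_aa_frequencies()]).
#' @return A list of class `similarity_config`.
#' @export
similarity_config <- function(T = 0.078, metric = c("euclidean", "blic"),
                              blic_alpha = rep(1, 20),
                              background = human_aa_frequencies()) {
  metric <- match.arg(metric)
  stopifnot(T > 0, length(blic_alpha) == 20L, all(blic_alpha > 0),
            length(background) == 20L, all(background > 0))
  structure(list(T = T, metric = metric, blic_alpha = blic_alpha,
                 background = background / sum(background)),
            class = "similarity_config")
}

#' Squared Euclidean distance between two PWMs
#'
#' `D^2 = (1/L) * sum over all L positions and 20 residues of the squared
#' entry differences`. Symmetric, zero iff the matrices are identical, and
#' bounded by 2 for valid PWMs. No cross-length comparison is defined.
#'
#' @param m1,m2 [pwm()] objects of equal length.
#' @return Non-negative scalar.
#' @export
#' @examples
#' motif_distance(uniform_pwm(9), uniform_pwm(9))  # 0
motif_distance <- function(m1, m2) {
  if (nrow(m1) != nrow(m2)) {
    stop("cannot compare PWMs of different lengths (", nrow(m1), " vs ",
         nrow(m2), ")")
  }
  sum((unclass(m1) - unclass(m2))^2) / nrow(m1)
}

#' Are two motifs similar?
#'
#' TRUE iff [motif_distance()] is at or below the threshold `T`.
#'
#' @inheritParams motif_distance
#' @param config A [similarity_config()].
#' @return Logical scalar.
#' @export
is_similar <- function(m1, m2, config = similarity_config()) {
  motif_distance(m1, m2) <= config$T
}

# log Dirichlet-multinomial marginal of one count column (multinomial
# coefficient omitted; it cancels in the BLiC ratios)
.log_dirmult <- function(counts, alpha) {
  lgamma(sum(alpha)) - sum(lgamma(alpha)) +
    sum(lgamma(counts + alpha)) - lgamma(sum(counts) + sum(alpha))
}

#' BLiC similarity score between two count matrices
#'
#' Bayesian likelihood-ratio column similarity under Dirichlet priors.
#' For each position the score is
#' `log[ P(c1 + c2) / (P(c1) P(c2)) ] + log[ P(c1 + c2) / Q(c1 + c2) ]`
#' where `P` is the Dirichlet-multinomial marginal with hyper-parameters
#' `blic_alpha` and `Q` the multinomial likelihood under the background
#' frequencies; multinomial coefficients are omitted uniformly. Position
#' scores are summed; larger values mean more similar columns.
#'
#' @param c1,c2 `L x 20` count matrices (see [count_matrix()]).
#' @param config A [similarity_config()].
#' @return Scalar score.
#' @export
blic_similarity <- function(c1, c2, config = similarity_config()) {
  if (nrow(c1) != nrow(c2)) stop("count matrices must have equal lengths")
  if (any(c1 < 0) || any(c2 < 0)) stop("counts must be non-negative")
  if (any(rowSums(c1) == 0) || any(rowSums(c2) == 0)) {
    stop("zero total counts at a position")
  }
  alpha <- config$blic_alpha
  q <- config$background
  total <- 0
  for (i in seq_len(nrow(c1))) {
    a <- c1[i, ]; b <- c2[i, ]; ab <- a + b
    joint <- .log_dirmult(ab, alpha)
    indep <- .log_dirmult(a, alpha) + .log_dirmult(b, alpha)
    bg <- sum(ab * log(q))
    total <- total + (joint - indep) + (joint - bg)
  }
  total
}

#' Reference motif library
#'
#' A compendium of per-allele reference PWMs (emulating motifs built from
#' curated ligand databases) with their supporting ligand counts. Used for
#' empirical similarity P-values and for the semi-supervised annotation
#' pass, where only entries with more than `min_ligands` ligands are
#' eligible.
#'
#' @param pwms Named list (allele or padding id -> [pwm()]).
#' @param n_ligands Named integer vector aligned with `pwms`.
#' @return A list of class `reference_library`.
#' @export
reference_library <- function(pwms, n_ligands) {
  stopifnot(length(pwms) == length(n_ligands), !is.null(names(pwms)))
  if (any(n_ligands < 1)) stop("n_ligands must be >= 1")
  names(n_ligands) <- names(pwms)
  structure(list(pwms = pwms, n_ligands = n_ligands),
            class = "reference_library")
}

#' Write / read a reference motif library
#'
#' On disk a library is a directory of PWM files (`<name>.pwm`, see
#' [write_pwm()]) plus an `index.tsv` with columns `allele` and
#' `n_ligands`.
#'
#' @param library A [reference_library()].
#' @param dir Directory path.
#' @return `read_reference_library` returns a [reference_library()].
#' @export
write_reference_library <- function(library, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(library$pwms)) {
    write_pwm(library$pwms[[nm]], file.path(dir, paste0(nm, ".pwm")))
  }
  utils::write.table(
    data.frame(allele = names(library$pwms),
               n_ligands = as.integer(library$n_ligands)),
    file.path(dir, "index.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_reference_library
#' @export
read_reference_library <- function(dir) {
  idx <- utils::read.delim(file.path(dir, "index.tsv"),
                           stringsAsFactors = FALSE)
  pwms <- lapply(idx$allele, function(a) read_pwm(file.path(dir, paste0(a, ".pwm"))))
  names(pwms) <- idx$allele
  reference_library(pwms, stats::setNames(idx$n_ligands, idx$allele))
}

#' Empirical P-value of a motif similarity
#'
#' Compares the similarity of `m1` and `m2` to the similarities between
#' `m1` and every motif of a reference library (optionally excluding the
#' allele `m1` is annotated to). With `d_obs` the observed distance and
#' `d_r` the reference distances, `P = (1 + #{d_r <= d_obs}) / (1 + N)`
#' (add-one correction, so `P` is never 0). For the BLiC metric the
#' inequality reverses (higher score = more similar); count matrices are
#' then reconstructed as `PWM * n` using `n1`/`n2` peptide counts.
#'
#' @inheritParams motif_distance
#' @param library A [reference_library()].
#' @param exclude Allele name(s) to drop from the reference set (the
#'   allele `m1` is annotated to), or `NULL`.
#' @param config A [similarity_config()].
#' @param n1,n2 Assigned-peptide counts behind `m1`/`m2` (BLiC metric
#'   only; reference motifs use their `n_ligands`).
#' @return P-value in (0, 1].
#' @export
empirical_similarity_pvalue <- function(m1, m2, library, exclude = NULL,
                                        config = similarity_config(),
                                        n1 = 100L, n2 = 100L) {
  keep <- setdiff(names(library$pwms), exclude)
  if (length(keep) == 0L) stop("reference library is empty after exclusion")
  refs <- library$pwms[keep]
  refs <- refs[vapply(refs, nrow, integer(1)) == nrow(m1)]
  if (length(refs) == 0L) stop("no reference motifs of length ", nrow(m1))
  if (config$metric == "euclidean") {
    d_obs <- motif_distance(m1, m2)
    d_ref <- vapply(refs, motif_distance, numeric(1), m2 = m1)
    hits <- sum(d_ref <= d_obs)
  } else {
    c1 <- unclass(m1) * n1
    s_obs <- blic_similarity(c1, unclass(m2) * n2, config)
    s_ref <- vapply(names(refs), function(a) {
      blic_similarity(c1, unclass(refs[[a]]) * library$n_ligands[[a]], config)
    }, numeric(1))
    hits <- sum(s_ref >= s_obs)
  }
  (1 + hits) / (1 + length(refs))
}
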