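#' Alleles excluded from the MS background estimate
#'
#' Alleles whose motifs show residual specificity at the middle positions
#' P4--P7 of 9-mers; they are excluded when estimating the
#' mass-spectrometry amino-acid background from pooled per-allele
#' peptides.
#'
#' @return Character vector of compact allele names.
#' @export
ms_background_excluded_alleles <- function() {
  c("A0201", "A0205", "A0206", "A0220", "A2501", "A2601", "A2902",
    "B0801", "B1401", "B1402", "C0303", "C0704")
}

#' Estimate the MS amino-acid background at non-anchor positions
#'
#' Computes residue frequencies over positions P4--P7 of the pooled 9-mer
#' peptides of each allele, then averages the per-allele frequency vectors
#' (unweighted) across all non-excluded alleles. Zero entries are floored
#' at `floor` (cysteine depletion in MS data makes zeros reachable) and
#' the vector renormalized.
#'
#' @param pools Named list: allele -> character vector of 9-mer peptides.
#' @param excluded Alleles to ignore (default
#'   [ms_background_excluded_alleles()]).
#' @param floor Lower bound applied to zero frequencies (default 1e-4).
#' @return Named numeric background vector over [aa_alphabet()], summing
#'   to 1.
#' @export
estimate_ms_background <- function(pools,
                                   excluded = ms_background_excluded_alleles(),
                                   floor = 1e-4) {
  use <- setdiff(names(pools), excluded)
  use <- use[vapply(use, function(a) length(pools[[a]]) > 0, logical(1))]
  use <- use[vapply(use, function(a) all(nchar(pools[[a]]) == 9L), logical(1))]
  if (length(use) == 0L) stop("no non-excluded alleles with 9-mer pools")
  freqs <- vapply(use, function(a) {
    cm <- count_matrix(pools[[a]])
    f <- colSums(cm[4:7, , drop = FALSE])
    f / sum(f)
  }, numeric(20))
  q <- rowMeans(freqs)
  q <- pmax(q, floor)
  q <- q / sum(q)
  stats::setNames(q, aa_alphabet())
}

#' Residue frequencies of a proteome, and Pearson correlation of two
#' background vectors
#'
#' `proteome_frequencies` counts canonical residues over all sequences;
#' `pearson_r` is the standard Pearson correlation of two length-20
#' frequency vectors (e.g. MS background vs proteome background).
#'
#' @param proteome Named character vector (id -> sequence).
#' @return Named numeric vector over [aa_alphabet()], summing to 1.
#' @export
proteome_frequencies <- function(proteome) {
  if (length(proteome) == 0L) stop("empty proteome")
  chars <- strsplit(paste(proteome, collapse = ""), "")[[1]]
  counts <- table(factor(chars, levels = aa_alphabet()))
  if (sum(counts) == 0L) stop("proteome contains no canonical residues")
  stats::setNames(as.numeric(counts) / sum(counts), aa_alphabet())
}

#' @rdname proteome_frequencies
#' @param q1,q2 Length-20 numeric vectors.
#' @export
pearson_r <- function(q1, q2) {
  if (stats::sd(q1) == 0 || stats::sd(q2) == 0) {
    stop("zero-variance frequency vector")
  }
  stats::cor(q1, q2)
}

#' Build a per-allele PWM with BLOSUM62 pseudocounts
#'
#' Per position, with `f` the observed residue frequencies and
#' `g = f %*% rho` the BLOSUM62-implied substitution frequencies, the PWM
#' entry is `p = (alpha * f + beta * g) / (alpha + beta)` with data weight
#' `alpha = n - 1` and pseudocount weight `beta` (default 200).
#'
#' @param peptides Character vector of equal-length training peptides.
#' @param params A [pseudocount_params()].
#' @return A [pwm()].
#' @export
build_allele_pwm <- function(peptides, params = pseudocount_params()) {
  if (length(peptides) < 1L) stop("need at least one training peptide")
  if (length(unique(nchar(peptides))) != 1L) {
    stop("training peptides must all have the same length")
  }
  cm <- count_matrix(peptides)
  n <- attr(cm, "n")
  f <- cm / rowSums(cm)
  g <- f %*% params$rho          # g[i, A] = sum_B f[i, B] * rho[B, A]
  alpha <- max(n - 1, 0)
  p <- (alpha * f + params$beta * g) / (alpha + params$beta)
  pwm(p / rowSums(p))
}

#' Train per-allele models from pooled peptides
#'
#' Builds a pseudocounted PWM per allele and per available length (9/10).
#'
#' @param pools Named list: allele -> character vector of peptides (mixed
#'   lengths allowed; 9- and 10-mers are modelled).
#' @param params A [pseudocount_params()].
#' @param lengths Lengths to model (default `c(9, 10)`).
#' @return Named list of `allele_model` objects: `list(allele, pwms =
#'   list("9" = pwm, ...), n = counts per length)`.
#' @export
build_allele_models <- function(pools, params = pseudocount_params(),
                                lengths = c(9L, 10L)) {
  models <- list()
  for (a in names(pools)) {
    by_len <- split(pools[[a]], nchar(pools[[a]]))
    by_len <- by_len[names(by_len) %in% as.character(lengths)]
    if (length(by_len) == 0L) next
    models[[a]] <- structure(list(
      allele = a,
      pwms = lapply(by_len, build_allele_pwm, params = params),
      n = lengths(by_len)
    ), class = "allele_model")
  }
  models
}

#' Score a peptide set against one PWM
#'
#' `S = (1/N) * sum_i ln( p[i, x_i] / q[x_i] )`: the length-normalized sum
#' of log PWM entries, renormalized by the expected (MS background)
#' amino-acid frequencies. Natural logarithm.
#'
#' @param peptides Character vector of peptides, same length as the PWM.
#' @param p A [pwm()].
#' @param q Length-20 background frequency vector (all entries > 0).
#' @return Numeric vector of scores.
#' @export
score_peptides <- function(peptides, p, q) {
  stopifnot(all(q > 0), length(q) == 20L)
  idx <- encode_peptides(peptides)
  if (ncol(idx) != nrow(p)) {
    stop("peptide length ", ncol(idx), " does not match PWM length ", nrow(p))
  }
  lp <- log(unclass(p))
  lq <- log(q)
  s <- numeric(nrow(idx))
  lp <- unname(lp)
  lq <- unname(lq)
  for (i in seq_len(ncol(idx))) {
    s <- s + lp[i, ][idx[, i]] - lq[idx[, i]]
  }
  s / ncol(idx)
}

#' Empirical score background for a model set
#'
#' Samples `n` random proteome peptides per length and records the
#' max-over-alleles score of each, the reference distribution for the
#' empirical P-values of [predict_peptides()].
#'
#' @param models Named list of allele models ([build_allele_models()]).
#' @param q Background frequency vector.
#' @param proteome Named character vector (id -> sequence).
#' @param n Background size per length (default 100000).
#' @param seed Integer seed.
#' @param lengths Peptide lengths to cover (default those of the models).
#' @return Named list: length -> sorted numeric vector of background
#'   scores.
#' @export
score_background <- function(models, q, proteome, n = 100000L, seed = 1L,
                             lengths = NULL) {
  if (is.null(lengths)) {
    lengths <- sort(unique(unlist(lapply(models, function(m) names(m$pwms)))))
  }
  out <- list()
  for (len in as.character(lengths)) {
    peps <- sample_random_peptides(proteome, as.integer(len), n,
                                   seed = seed + as.integer(len))
    sc <- .max_scores(peps, models, q, len)
    out[[len]] <- sort(sc$best_score)
  }
  out
}

# per-allele scores + max over alleles for equal-length peptides
.max_scores <- function(peptides, models, q, len) {
  have <- Filter(function(m) len %in% names(m$pwms), models)
  if (length(have) == 0L) stop("no model covers length ", len)
  mat <- vapply(have, function(m) score_peptides(peptides, m$pwms[[len]], q),
                numeric(length(peptides)))
  if (length(peptides) == 1L) mat <- matrix(mat, nrow = 1L,
                                            dimnames = list(NULL, names(have)))
  best <- max.col(mat, ties.method = "first")
  list(per_allele = mat,
       best_allele = names(have)[best],
       best_score = mat[cbind(seq_along(peptides), best)])
}

#' Score peptides against allele models with empirical P-values
#'
#' The score of a peptide is the maximum of its per-allele PWM scores; the
#' empirical P-value compares it to the background score distribution:
#' `P = (1 + #{background >= S}) / (1 + N_background)`. Records are sorted
#' by descending score, ties broken lexicographically by peptide sequence.
#'
#' @param peptides Character vector (9- and/or 10-mers).
#' @param models Named list of allele models.
#' @param q Background frequency vector.
#' @param background A [score_background()] result covering the peptide
#'   lengths.
#' @return Data frame with columns `peptide`, `length`, `best_allele`,
#'   `score`, `p_value` and 1-based `rank`.
#' @export
predict_peptides <- function(peptides, models, q, background) {
  if (length(peptides) == 0L) {
    return(data.frame(peptide = character(0), length = integer(0),
                      best_allele = character(0), score = numeric(0),
                      p_value = numeric(0), rank = integer(0)))
  }
  rows <- lapply(split(peptides, nchar(peptides)), function(peps) {
    len <- as.character(nchar(peps[1]))
    bg <- background[[len]]
    if (is.null(bg) || length(bg) == 0L) {
      stop("no background scores for length ", len)
    }
    sc <- .max_scores(peps, models, q, len)
    n_ge <- length(bg) - findInterval(sc$best_score, bg)  # bg sorted ascending
    data.frame(peptide = peps, length = as.integer(len),
               best_allele = sc$best_allele, score = sc$best_score,
               p_value = (1 + n_ge) / (1 + length(bg)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$peptide), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Enumerate candidate neo-antigen peptides for missense mutations
#'
#' For each mutation record, all 9- and 10-mer windows of the protein that
#' cover the mutated position are generated with the alternate residue
#' substituted; the union over records is deduplicated by sequence.
#'
#' @param mutations Data frame with columns `protein_id`, `position`
#'   (1-based), `ref`, `alt`, and either a `sequence` column or entries in
#'   `proteome`.
#' @param proteome Optional named character vector supplying protein
#'   sequences by `protein_id`.
#' @param lengths Window lengths (default `c(9, 10)`).
#' @return Character vector of unique mutated peptides.
#' @export
enumerate_missense_candidates <- function(mutations, proteome = NULL,
                                          lengths = c(9L, 10L)) {
  out <- character(0)
  for (r in seq_len(nrow(mutations))) {
    seqs <- if (!is.null(mutations$sequence)) mutations$sequence[r]
            else proteome[[mutations$protein_id[r]]]
    if (is.null(seqs)) stop("no sequence for protein ", mutations$protein_id[r])
    pos <- mutations$position[r]
    if (substr(seqs, pos, pos) != mutations$ref[r]) {
      stop("reference residue mismatch for ", mutations$protein_id[r],
           " position ", pos)
    }
    if (identical(mutations$ref[r], mutations$alt[r])) {
      stop("ref and alt residues are identical for ",
           mutations$protein_id[r], " position ", pos)
    }
    mut_seq <- seqs
    substr(mut_seq, pos, pos) <- mutations$alt[r]
    plen <- nchar(mut_seq)
    for (L in lengths) {
      lo <- max(1L, pos - L + 1L)
      hi <- min(pos, plen - L + 1L)
      if (hi < lo) next        # protein shorter than the window
      starts <- lo:hi
      out <- c(out, substring(mut_seq, starts, starts + L - 1L))
    }
  }
  unique(out[is_canonical_peptide(out)])
}

#' Rank neo-antigen candidates for one patient
#'
#' Enumerates mutated peptides, scores them with the patient's allele
#' models (HLA-A and HLA-B only by default, as HLA-C alleles are weakly
#' expressed) and returns the prediction table ranked by descending score.
#' The rank of a designated peptide is the number of peptides one would
#' need to test to reach it.
#'
#' @param mutations Mutation table (see
#'   [enumerate_missense_candidates()]).
#' @param models Named list of allele models for the patient's genotype.
#' @param q Background frequency vector.
#' @param background A [score_background()] result.
#' @param proteome Optional proteome for mutation sequences.
#' @param include_C Include HLA-C models (default FALSE).
#' @param lengths Candidate window lengths (default `c(9, 10)`).
#' @return The [predict_peptides()] data frame over all candidates.
#' @export
rank_neoantigens <- function(mutations, models, q, background,
                             proteome = NULL, include_C = FALSE,
                             lengths = c(9L, 10L)) {
  if (!include_C) {
    models <- models[allele_locus(names(models)) %in% c("A", "B")]
  }
  if (length(models) == 0L) stop("no HLA-A/B models available")
  cands <- enumerate_missense_candidates(mutations, proteome,
                                         lengths = lengths)
  predict_peptides(cands, models, q, background)
}

#' Benchmark a score set: AUC and PP1%
#'
#' AUC by the rank statistic (ties contribute 1/2); PP1% is the fraction
#' of positives among the top `ceil(0.01 * n)` scores. With a 99-fold
#' decoy excess PP1% equals both precision and recall at the top-1%
#' cutoff.
#'
#' @param scores Numeric vector.
#' @param is_positive Logical vector aligned with `scores`.
#' @return List with `auc`, `pp1`, `n_pos`, `n_neg`.
#' @export
evaluate_predictions <- function(scores, is_positive) {
  stopifnot(length(scores) == length(is_positive))
  n_pos <- sum(is_positive)
  n_neg <- sum(!is_positive)
  if (n_pos == 0L || n_neg == 0L) {
    stop("need at least one positive and one negative")
  }
  r <- rank(scores)                     # mean rank for ties -> 1/2 per tie
  auc <- (sum(r[is_positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  top <- ceiling(0.01 * length(scores))
  ord <- order(-scores)
  pp1 <- sum(is_positive[ord[seq_len(top)]]) / top
  list(auc = auc, pp1 = pp1, n_pos = n_pos, n_neg = n_neg)
}

#' Remove peptides with a tryptic signature
#'
#' Drops peptides ending in R or K (a tryptic digestion artefact in MS
#' data) unless the allele genuinely prefers basic C-terminal residues
#' (default exceptions A03:01 and A31:01).
#'
#' @param peptides Character vector.
#' @param allele Allele the peptides belong to.
#' @param exceptions Alleles whose motifs legitimately end in R/K.
#' @return Filtered character vector.
#' @export
filter_tryptic_signature <- function(peptides, allele,
                                     exceptions = c("A0301", "A3101")) {
  if (length(peptides) == 0L) return(peptides)
  if (parse_allele(allele) %in% parse_allele(exceptions)) return(peptides)
  peptides[!grepl("[RK]$", peptides)]
}
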