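#' Generate ground-truth allele motifs
#'
#' Builds a truth specification: one PWM per allele and length with anchor
#' positions at P2 and the C-terminus. Anchor residues are sampled without
#' replacement across alleles at each anchor position, so any two alleles
#' differ at both anchors and all pairwise truth distances exceed twice
#' the annotation threshold; cysteine is excluded from the anchor
#' candidates (it is depleted in MS data, which would blur the anchor).
#' Non-anchor positions follow the human-like background. Optional
#' confusable pairs share both anchors and differ only by a small
#' perturbation (truth distance below the threshold), emulating
#' near-identical allele pairs.
#'
#' @param n_alleles Number of alleles (at most 19 distinguishable).
#' @param lengths Peptide lengths to generate PWMs for (default 9).
#' @param seed Integer seed.
#' @param anchor_prob Probability mass on the anchor residue (default 0.9).
#' @param loci Optional character vector assigning a locus (`"A"/"B"/"C"`)
#'   to each allele; defaults to cycling A, B, C.
#' @param confusable_pairs Number of additional alleles appended as
#'   near-duplicates of the first alleles (default 0).
#' @param background Length-20 non-anchor residue distribution (default
#'   [human_aa_frequencies()]).
#' @return A list of class `truth_spec`: `alleles`, `pwms[[allele]][[len]]`,
#'   `anchors` (data frame), `anchor_prob`, `background`.
#' @export
generate_truth <- function(n_alleles, lengths = 9L, seed = 1L,
                           anchor_prob = 0.9, loci = NULL,
                           confusable_pairs = 0L,
                           background = human_aa_frequencies()) {
  stopifnot(n_alleles >= 1)
  anchor_pool <- setdiff(aa_alphabet(), "C")
  if (n_alleles > length(anchor_pool)) {
    stop("more alleles (", n_alleles, ") than distinguishable anchor ",
         "combinations (", length(anchor_pool), ")")
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  if (is.null(loci)) loci <- rep(c("A", "B", "C"), length.out = n_alleles)
  stopifnot(length(loci) == n_alleles)
  alleles <- character(n_alleles)
  for (lc in unique(loci)) {
    k <- sum(loci == lc)
    alleles[loci == lc] <- sprintf("%s%02d01", lc, seq_len(k))
  }

  a2 <- sample(anchor_pool, n_alleles)
  aL <- sample(anchor_pool, n_alleles)

  anchored_pwm <- function(L, r2, rL) {
    m <- matrix(rep(background, each = L), nrow = L)
    put <- function(m, i, r) {
      row <- background
      row[r] <- 0
      row <- row / sum(row) * (1 - anchor_prob)
      row[r] <- anchor_prob
      m[i, ] <- row
      m
    }
    m <- put(m, 2L, r2)
    m <- put(m, L, rL)
    pwm(m)
  }

  pwms <- lapply(seq_len(n_alleles), function(j) {
    ps <- lapply(lengths, function(L) anchored_pwm(L, a2[j], aL[j]))
    names(ps) <- as.character(lengths)
    ps
  })
  names(pwms) <- alleles
  anchors <- data.frame(allele = alleles, p2 = a2, pC = aL,
                        stringsAsFactors = FALSE)

  if (confusable_pairs > 0L) {
    for (j in seq_len(confusable_pairs)) {
      twin <- sprintf("%s%02d02", substr(alleles[j], 1, 3), j)
      tp <- lapply(pwms[[j]], function(p) {
        m <- unclass(p)
        # perturb non-anchor rows slightly; keeps D^2 well under T
        mid <- setdiff(seq_len(nrow(m)), c(2L, nrow(m)))
        m[mid, ] <- m[mid, ] + 0.02
        pwm(m / rowSums(m))
      })
      pwms[[twin]] <- tp
      alleles <- c(alleles, twin)
      anchors <- rbind(anchors, data.frame(allele = twin, p2 = a2[j],
                                           pC = aL[j]))
    }
  }

  structure(list(alleles = alleles, pwms = pwms, anchors = anchors,
                 anchor_prob = anchor_prob, background = background,
                 lengths = as.integer(lengths), seed = as.integer(seed)),
            class = "truth_spec")
}

#' Cohort design: samples, genotypes, sizes, noise
#'
#' @param samples Data frame with columns `sample_id` and `alleles`
#'   (comma-separated compact names).
#' @param peptides_per_sample Peptides drawn per sample and length
#'   (default 4000).
#' @param contaminant_fraction Fraction of peptides replaced by uniform
#'   random sequences (default 0).
#' @param mixing `"uniform"` or a named list sample_id -> numeric weights
#'   over the genotype alleles.
#' @param cysteine_depletion Multiplicative detection bias applied to
#'   cysteine when sampling peptides (default 0.2; the truth PWMs are
#'   unbiased, the bias lives in the data as in real MS).
#' @param seed Integer seed.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(samples, peptides_per_sample = 4000L,
                          contaminant_fraction = 0,
                          mixing = "uniform",
                          cysteine_depletion = 0.2,
                          seed = 1L) {
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "alleles") %in% names(samples)),
            peptides_per_sample >= 1,
            contaminant_fraction >= 0, contaminant_fraction < 1,
            cysteine_depletion >= 0)
  structure(list(samples = samples,
                 peptides_per_sample = as.integer(peptides_per_sample),
                 contaminant_fraction = contaminant_fraction,
                 mixing = mixing,
                 cysteine_depletion = cysteine_depletion,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' The standard multi-sample cohort design
#'
#' Ten samples over fifteen alleles (five HLA-A, six HLA-B, four HLA-C)
#' with a genotype incidence built so that each co-occurrence annotation
#' rule has work to do: most alleles are shared by two to four samples
#' (rule 1), sample S07 carries exactly the genotype of S01 minus C01:01
#' so the extra motif identifies that allele (rule 2), and B06:01 occurs
#' only in S05 where it is the last remaining motif once the rest of the
#' genotype is annotated (rule 3).
#'
#' @param peptides_per_sample,contaminant_fraction,seed Passed through to
#'   [cohort_design()].
#' @return A [cohort_design()].
#' @export
standard_cohort_design <- function(peptides_per_sample = 4000L,
                                   contaminant_fraction = 0,
                                   seed = 1L) {
  g <- c(
    S01 = "A0101,A0201,B0101,B0201,C0101",
    S02 = "A0101,A0401,B0101,B0301,C0201",
    S03 = "A0201,A0401,B0101,B0301,C0301",
    S04 = "A0301,A0501,B0401,B0501,C0401",
    S05 = "A0301,A0101,B0101,B0601,C0301",
    S06 = "A0501,A0401,B0501,B0101,C0201",
    S07 = "A0101,A0201,B0101,B0201",
    S08 = "A0301,B0401,C0401",
    S09 = "A0501,B0301,C0301",
    S10 = "A0401,B0301,C0401"
  )
  cohort_design(
    data.frame(sample_id = names(g), alleles = unname(g),
               stringsAsFactors = FALSE),
    peptides_per_sample = peptides_per_sample,
    contaminant_fraction = contaminant_fraction,
    seed = seed)
}

#' Truth spec matching [standard_cohort_design()]
#'
#' Fifteen alleles with the loci used by the standard design.
#'
#' @param seed,lengths Passed to [generate_truth()].
#' @return A `truth_spec`.
#' @export
standard_truth <- function(seed = 1L, lengths = 9L) {
  generate_truth(15L, lengths = lengths, seed = seed,
                 loci = rep(c("A", "B", "C"), times = c(5, 6, 4)))
}

#' Generate a synthetic multi-sample cohort
#'
#' Draws each sample's peptides from its genotype alleles' truth PWMs
#' according to the mixing weights, applies the cysteine detection bias,
#' replaces `contaminant_fraction` of the peptides with uniform random
#' sequences, deduplicates per sample, and keeps the ground-truth
#' peptide-to-allele labels as a sidecar for oracle tests.
#'
#' @param truth A `truth_spec`.
#' @param design A [cohort_design()]; every genotype allele must exist in
#'   the truth.
#' @return A list of class `synthetic_cohort`: `samples` (list of
#'   [sample_dataset()]), `labels` (data frame sample_id, peptide, length,
#'   allele -- `"contaminant"` for injected noise), `truth`, `design`.
#' @export
generate_cohort <- function(truth, design) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(design$seed)

  bias <- rep(1, 20)
  names(bias) <- aa_alphabet()
  bias["C"] <- design$cysteine_depletion

  samples <- list()
  labels <- list()
  for (r in seq_len(nrow(design$samples))) {
    sid <- design$samples$sample_id[r]
    genotype <- validate_genotype(
      strsplit(design$samples$alleles[r], ",")[[1]], sid)
    missing <- setdiff(genotype, truth$alleles)
    if (length(missing)) {
      stop("design allele(s) absent from truth: ", paste(missing, collapse = ", "))
    }
    w <- if (identical(design$mixing, "uniform")) {
      rep(1 / length(genotype), length(genotype))
    } else {
      wi <- design$mixing[[sid]]
      stopifnot(length(wi) == length(genotype), abs(sum(wi) - 1) < 1e-9)
      wi
    }
    by_len <- list()
    for (len in as.character(truth$lengths)) {
      n <- design$peptides_per_sample
      n_cont <- round(design$contaminant_fraction * n)
      n_real <- n - n_cont
      counts <- as.vector(stats::rmultinom(1, n_real, w))
      peps <- character(0); labs <- character(0)
      for (j in seq_along(genotype)) {
        if (counts[j] == 0) next
        pj <- sample_from_pwm(truth$pwms[[genotype[j]]][[len]], counts[j],
                              bias = bias)
        peps <- c(peps, pj)
        labs <- c(labs, rep(genotype[j], counts[j]))
      }
      if (n_cont > 0) {
        L <- as.integer(len)
        cont <- sample_from_pwm(uniform_pwm(L), n_cont)
        peps <- c(peps, cont)
        labs <- c(labs, rep("contaminant", n_cont))
      }
      keep <- !duplicated(peps)
      by_len[[len]] <- peps[keep]
      labels[[length(labels) + 1L]] <- data.frame(
        sample_id = sid, peptide = peps[keep], length = as.integer(len),
        allele = labs[keep], stringsAsFactors = FALSE)
    }
    samples[[sid]] <- sample_dataset(sid, genotype, by_len)
  }
  structure(list(samples = samples, labels = do.call(rbind, labels),
                 truth = truth, design = design),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Emits the manifest + peptide lists ([write_manifest()]), the truth
#' labels as `truth_labels.tsv` and the truth PWMs as PWM files under
#' `truth_pwms/`, the layout consumed by the command-line interface.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_manifest(cohort$samples, dir)
  utils::write.table(cohort$labels, file.path(dir, "truth_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pdir <- file.path(dir, "truth_pwms")
  dir.create(pdir, showWarnings = FALSE)
  for (a in names(cohort$truth$pwms)) {
    for (len in names(cohort$truth$pwms[[a]])) {
      write_pwm(cohort$truth$pwms[[a]][[len]],
                file.path(pdir, sprintf("%s_%s.pwm", a, len)))
    }
  }
  invisible(dir)
}

#' Generate a reference motif library from truth alleles
#'
#' Emulates a curated-ligand motif compendium: for each requested allele,
#' `ligand_counts` peptides are sampled from its truth PWM and converted
#' to a flat +1-count PWM ([build_reference_pwm()]). Padding motifs with
#' fresh random anchors can be appended to reach a target compendium size
#' (e.g. 107 reference motifs for the empirical P-values).
#'
#' @param truth A `truth_spec`.
#' @param alleles Subset of truth alleles to include.
#' @param ligand_counts Integer (recycled) or named vector of per-allele
#'   ligand counts.
#' @param n_padding Number of unrelated padding motifs (default 0).
#' @param length Peptide length (default 9).
#' @param seed Integer seed.
#' @return A [reference_library()].
#' @export
generate_reference_library <- function(truth, alleles = truth$alleles,
                                       ligand_counts = 100L, n_padding = 0L,
                                       length = 9L, seed = 1L) {
  stopifnot(all(alleles %in% truth$alleles))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  counts <- if (is.null(names(ligand_counts))) {
    stats::setNames(rep(ligand_counts, length.out = base::length(alleles)), alleles)
  } else ligand_counts[alleles]
  pwms <- lapply(alleles, function(a) {
    build_reference_pwm(sample_from_pwm(truth$pwms[[a]][[as.character(length)]],
                                        counts[[a]]))
  })
  names(pwms) <- alleles
  n_ligands <- counts
  if (n_padding > 0L) {
    pads <- random_reference_motifs(n_padding, length = length,
                                    background = truth$background,
                                    anchor_prob = truth$anchor_prob)
    names(pads) <- sprintf("PAD%03d", seq_len(n_padding))
    pwms <- c(pwms, pads)
    n_ligands <- c(n_ligands,
                   stats::setNames(rep(100L, n_padding), names(pads)))
  }
  reference_library(pwms, n_ligands)
}

#' Random anchored reference motifs
#'
#' Draws motifs with independently random P2 / C-terminal anchors over the
#' human-like background -- the null generator behind the empirical
#' P-value calibration.
#'
#' @param n Number of motifs.
#' @param length Peptide length.
#' @param background Non-anchor residue distribution.
#' @param anchor_prob Anchor mass.
#' @return List of [pwm()] objects.
#' @export
random_reference_motifs <- function(n, length = 9L,
                                    background = human_aa_frequencies(),
                                    anchor_prob = 0.9) {
  pool <- setdiff(aa_alphabet(), "C")
  lapply(seq_len(n), function(j) {
    m <- matrix(rep(background, each = length), nrow = length)
    for (i in c(2L, length)) {
      r <- sample(pool, 1)
      row <- background
      row[r] <- 0
      row <- row / sum(row) * (1 - anchor_prob)
      row[r] <- anchor_prob
      m[i, ] <- row
    }
    pwm(m)
  })
}

#' Generate a synthetic proteome and missense-mutation table
#'
#' Protein sequences are drawn i.i.d. from the human-like residue
#' frequencies; mutations are placed uniformly with `alt != ref`.
#' Optionally one neo-antigen is planted: a window is rewritten so that,
#' once the mutation's alternate residue is substituted, the mutated
#' peptide carries a chosen allele's anchor residues (the wild-type
#' sequence does not).
#'
#' @param n_proteins,protein_length,n_mutations Sizes.
#' @param seed Integer seed.
#' @param plant Optional list `list(truth =, allele =, length = 9L)`
#'   requesting a planted neo-antigen for `allele`.
#' @return List with `proteome` (named character), `mutations` (data frame
#'   `protein_id`, `position`, `ref`, `alt`) and `planted` (`NULL` or list
#'   with `peptide`, `allele`, `protein_id`, `position`).
#' @export
generate_proteome_and_mutations <- function(n_proteins = 50L,
                                            protein_length = 500L,
                                            n_mutations = 50L, seed = 1L,
                                            plant = NULL) {
  stopifnot(n_proteins >= 1, protein_length >= 10, n_mutations >= 0)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  bg <- human_aa_frequencies()
  ab <- aa_alphabet()
  proteome <- vapply(seq_len(n_proteins), function(j) {
    paste(sample(ab, protein_length, replace = TRUE, prob = bg), collapse = "")
  }, character(1))
  names(proteome) <- sprintf("PROT%03d", seq_len(n_proteins))

  planted <- NULL
  plant_row <- NULL
  if (!is.null(plant)) {
    L <- if (is.null(plant$length)) 9L else as.integer(plant$length)
    anch <- plant$truth$anchors
    a2 <- anch$p2[anch$allele == plant$allele]
    aC <- anch$pC[anch$allele == plant$allele]
    stopifnot(length(a2) == 1L)
    pid <- names(proteome)[1]
    s <- 11L                                  # window start, fixed
    seqs <- proteome[[pid]]
    # wild-type window carries the P2 anchor; the mutation creates the
    # C-terminal anchor, so only the mutated peptide matches the motif
    substr(seqs, s + 1L, s + 1L) <- a2
    pos <- s + L - 1L
    if (substr(seqs, pos, pos) == aC) {       # force a real change
      substr(seqs, pos, pos) <- setdiff(ab, c(aC, "C"))[1]
    }
    ref <- substr(seqs, pos, pos)
    proteome[[pid]] <- seqs
    plant_row <- data.frame(protein_id = pid, position = pos,
                            ref = ref, alt = aC, stringsAsFactors = FALSE)
    peptide <- substr(seqs, s, s + L - 1L)
    substr(peptide, L, L) <- aC
    planted <- list(peptide = peptide, allele = plant$allele,
                    protein_id = pid, position = pos)
  }

  # mutations are sampled from the (possibly edited) proteome so ref
  # residues always match the emitted sequences
  mut <- data.frame(protein_id = character(0), position = integer(0),
                    ref = character(0), alt = character(0),
                    stringsAsFactors = FALSE)
  if (n_mutations > 0) {
    pid <- sample(names(proteome), n_mutations, replace = TRUE)
    pos <- sample.int(protein_length, n_mutations, replace = TRUE)
    ref <- substring(proteome[pid], pos, pos)
    alt <- vapply(ref, function(r) sample(setdiff(ab, r), 1), character(1))
    mut <- data.frame(protein_id = pid, position = pos, ref = unname(ref),
                      alt = unname(alt), stringsAsFactors = FALSE)
    if (!is.null(plant_row)) {
      clash <- mut$protein_id == plant_row$protein_id &
        abs(mut$position - plant_row$position) < 25L
      mut <- mut[!clash, , drop = FALSE]
    }
  }
  if (!is.null(plant_row)) mut <- rbind(mut, plant_row)
  rownames(mut) <- NULL
  list(proteome = proteome, mutations = mut, planted = planted)
}
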