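#' Build a motif catalog from deconvoluted samples
#'
#' Runs the two-stage deconvolution ([deconvolve_sample()]) on every sample
#' for one peptide length and collects, per sample, the stage-2 motifs:
#' their PWMs, hard-assigned peptides and counts. This is the input of the
#' co-occurrence annotation.
#'
#' @param samples List of [sample_dataset()] objects.
#' @param length Peptide length (9 or 10).
#' @param config A [deconv_config()].
#' @return A list of class `motif_catalog`: per sample id, a list of
#'   motifs `list(index, pwm, peptides, n)`, plus attributes `length` and
#'   `genotypes` (named list sample id -> genotype).
#' @export
build_motif_catalog <- function(samples, length = 9L, config = deconv_config()) {
  entries <- list()
  genotypes <- list()
  for (s in samples) {
    # only the stage-2 (BIC-selected) model feeds the catalog; the fixed-K
    # stage-1 fit of deconvolve_sample is not needed here
    peptides <- s$peptides_by_length[[as.character(length)]]
    if (is.null(peptides) || base::length(peptides) == 0L) {
      stop("sample ", s$sample_id, " has no ", length, "-mers")
    }
    stage2 <- select_num_motifs(peptides, base::length(s$genotype) + 1L,
                                config,
                                trash = isTRUE(config$background_component))
    asn <- assign_peptides(stage2)
    motifs <- lapply(seq_len(stage2$K), function(k) {
      keep <- which(asn$motif == k)
      list(index = k, pwm = stage2$pwms[[k]],
           peptides = asn$peptide[keep],
           n = length(keep))
    })
    entries[[s$sample_id]] <- motifs
    genotypes[[s$sample_id]] <- s$genotype
  }
  structure(entries, length = length, genotypes = genotypes,
            class = "motif_catalog")
}

#' Assemble a motif catalog from pre-computed motifs
#'
#' Escape hatch for tests and for catalogs deconvoluted elsewhere: takes
#' per-sample motif lists directly.
#'
#' @param motifs Named list: sample id -> list of `list(index, pwm,
#'   peptides, n)`.
#' @param genotypes Named list: sample id -> character vector of alleles.
#' @param length Peptide length.
#' @return A `motif_catalog`.
#' @export
motif_catalog <- function(motifs, genotypes, length = 9L) {
  stopifnot(identical(sort(names(motifs)), sort(names(genotypes))))
  genotypes <- lapply(names(motifs), function(s)
    validate_genotype(genotypes[[s]], s))
  names(genotypes) <- names(motifs)
  structure(motifs, length = length, genotypes = genotypes,
            class = "motif_catalog")
}

# ---- annotation state ------------------------------------------------------

# The state is a data frame of assignments (sample_id, motif_index, allele,
# rule) plus the catalog-wide motif table. Motif keys are "sample|index".

.motif_key <- function(sample_id, index) paste(sample_id, index, sep = "|")

#' Create an empty annotation state for a catalog
#'
#' @param catalog A `motif_catalog`.
#' @return A list of class `annotation_state` with the (initially empty)
#'   assignment table.
#' @export
annotation_state <- function(catalog) {
  structure(list(
    assignments = data.frame(sample_id = character(0),
                             motif_index = integer(0),
                             allele = character(0),
                             rule = character(0),
                             stringsAsFactors = FALSE)
  ), class = "annotation_state")
}

#' @export
print.annotation_state <- function(x, ...) {
  cat("Annotation state:", nrow(x$assignments), "motif-allele assignments\n")
  if (nrow(x$assignments)) print(x$assignments)
  invisible(x)
}

.assigned_key <- function(state) {
  .motif_key(state$assignments$sample_id, state$assignments$motif_index)
}

# alleles already annotated within a sample
.annotated_alleles_in_sample <- function(state, sample_id) {
  state$assignments$allele[state$assignments$sample_id == sample_id]
}

.unannotated_motifs <- function(catalog, state, sample_id) {
  keys <- .assigned_key(state)
  Filter(function(m) !(.motif_key(sample_id, m$index) %in% keys),
         catalog[[sample_id]])
}

.add_assignment <- function(state, sample_id, motif_index, allele, rule) {
  state$assignments <- rbind(state$assignments, data.frame(
    sample_id = sample_id, motif_index = as.integer(motif_index),
    allele = allele, rule = rule, stringsAsFactors = FALSE))
  state
}

# pairwise D^2 lookup across the whole catalog, computed once
.catalog_distances <- function(catalog) {
  keys <- character(0); pwms <- list()
  for (s in names(catalog)) {
    for (m in catalog[[s]]) {
      keys <- c(keys, .motif_key(s, m$index))
      pwms <- c(pwms, list(m$pwm))
    }
  }
  n <- length(keys)
  d <- matrix(0, n, n, dimnames = list(keys, keys))
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- motif_distance(pwms[[i]], pwms[[j]])
    }
  }
  d
}

# enumerate selections of one candidate motif per sample forming a clique
# (all pairwise distances <= T); stops after finding `cap` cliques
.find_cliques <- function(cand_keys_by_sample, dist, T, cap = 2L) {
  found <- list()
  samples <- names(cand_keys_by_sample)
  recurse <- function(chosen, depth) {
    if (length(found) >= cap) return()
    if (depth > length(samples)) {
      found[[length(found) + 1L]] <<- chosen
      return()
    }
    for (key in cand_keys_by_sample[[depth]]) {
      if (all(dist[key, chosen] <= T)) {
        recurse(c(chosen, key), depth + 1L)
        if (length(found) >= cap) return()
      }
    }
  }
  recurse(character(0), 1L)
  found
}

# ---- the four co-occurrence rules -----------------------------------------

#' Annotation rule 1: motif shared across samples sharing an allele
#'
#' For every allele carried by at least two samples and not yet annotated
#' anywhere, searches for a selection of exactly one unannotated motif per
#' sharing sample such that all pairs are within the distance threshold.
#' If exactly one such mutually consistent clique exists, all its motifs
#' are annotated to the allele.
#'
#' @param catalog A `motif_catalog`.
#' @param state An `annotation_state`.
#' @param config A [similarity_config()].
#' @param dist Optional precomputed catalog distance matrix.
#' @return Updated `annotation_state`.
#' @export
rule1_shared_allele <- function(catalog, state, config = similarity_config(),
                                dist = NULL) {
  if (is.null(dist)) dist <- .catalog_distances(catalog)
  genotypes <- attr(catalog, "genotypes")
  alleles <- unique(unlist(genotypes))
  for (h in alleles) {
    if (h %in% state$assignments$allele) next
    sharing <- names(genotypes)[vapply(genotypes, function(g) h %in% g, logical(1))]
    if (length(sharing) < 2L) next
    cands <- lapply(sharing, function(s) {
      vapply(.unannotated_motifs(catalog, state, s),
             function(m) .motif_key(s, m$index), character(1))
    })
    names(cands) <- sharing
    if (any(lengths(cands) == 0L)) next
    cliques <- .find_cliques(cands, dist, config$T)
    if (length(cliques) != 1L) next
    for (key in cliques[[1]]) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      state <- .add_assignment(state, parts[1], as.integer(parts[2]), h, "1")
    }
  }
  state
}

#' Annotation rule 2: all-but-one-allele sample pairs
#'
#' If sample A's genotype is sample B's plus exactly one extra allele, and
#' exactly one of A's motifs has no counterpart within the threshold among
#' B's motifs, that motif is annotated to the extra allele (provided both
#' motif and allele are still unannotated in A).
#'
#' @inheritParams rule1_shared_allele
#' @return Updated `annotation_state`.
#' @export
rule2_all_but_one <- function(catalog, state, config = similarity_config(),
                              dist = NULL) {
  if (is.null(dist)) dist <- .catalog_distances(catalog)
  genotypes <- attr(catalog, "genotypes")
  ids <- names(genotypes)
  for (a_id in ids) for (b_id in ids) {
    if (a_id == b_id) next
    extra <- setdiff(genotypes[[a_id]], genotypes[[b_id]])
    if (length(extra) != 1L ||
        length(setdiff(genotypes[[b_id]], genotypes[[a_id]])) != 0L) next
    if (extra %in% .annotated_alleles_in_sample(state, a_id)) next
    a_keys <- vapply(catalog[[a_id]], function(m) .motif_key(a_id, m$index),
                     character(1))
    b_keys <- vapply(catalog[[b_id]], function(m) .motif_key(b_id, m$index),
                     character(1))
    if (length(b_keys) == 0L) next
    unmatched <- a_keys[vapply(a_keys, function(k)
      all(dist[k, b_keys] > config$T), logical(1))]
    if (length(unmatched) != 1L) next
    assigned <- .assigned_key(state)
    if (unmatched %in% assigned) next
    parts <- strsplit(unmatched, "|", fixed = TRUE)[[1]]
    state <- .add_assignment(state, parts[1], as.integer(parts[2]), extra, "2")
  }
  state
}

#' Annotation rule 3: last remaining motif and allele
#'
#' In any sample with exactly one unannotated motif and exactly one
#' genotype allele without an annotated motif, the two are matched.
#'
#' @inheritParams rule1_shared_allele
#' @return Updated `annotation_state`.
#' @export
rule3_last_remaining <- function(catalog, state, config = similarity_config()) {
  genotypes <- attr(catalog, "genotypes")
  for (s in names(genotypes)) {
    un_motifs <- .unannotated_motifs(catalog, state, s)
    un_alleles <- setdiff(genotypes[[s]], .annotated_alleles_in_sample(state, s))
    if (length(un_motifs) == 1L && length(un_alleles) == 1L) {
      state <- .add_assignment(state, s, un_motifs[[1]]$index, un_alleles, "3")
    }
  }
  state
}

#' Annotation rule 4: propagate annotated motifs by similarity
#'
#' For every allele with at least one annotated motif, and every sample
#' carrying that allele where it is still unannotated: if exactly one
#' unannotated motif of the sample is within the threshold of all of the
#' allele's annotated motifs, it is annotated to the allele.
#'
#' @inheritParams rule1_shared_allele
#' @return Updated `annotation_state`.
#' @export
rule4_propagate <- function(catalog, state, config = similarity_config(),
                            dist = NULL) {
  if (is.null(dist)) dist <- .catalog_distances(catalog)
  genotypes <- attr(catalog, "genotypes")
  for (h in unique(state$assignments$allele)) {
    anno <- state$assignments[state$assignments$allele == h, ]
    anno_keys <- .motif_key(anno$sample_id, anno$motif_index)
    carriers <- names(genotypes)[vapply(genotypes, function(g) h %in% g,
                                        logical(1))]
    for (s in setdiff(carriers, anno$sample_id)) {
      cand <- .unannotated_motifs(catalog, state, s)
      cand_keys <- vapply(cand, function(m) .motif_key(s, m$index), character(1))
      hits <- cand_keys[vapply(cand_keys, function(k)
        all(dist[k, anno_keys] <= config$T), logical(1))]
      if (length(hits) == 1L) {
        parts <- strsplit(hits, "|", fixed = TRUE)[[1]]
        state <- .add_assignment(state, parts[1], as.integer(parts[2]), h, "4")
      }
    }
  }
  state
}

#' Eliminate inconsistent same-allele motifs
#'
#' For each allele, while any pair of its annotated motifs is farther than
#' the threshold, the motif with the largest mean distance to the allele's
#' other motifs is returned to the unannotated pool; exact ties are all
#' removed (so a mutually inconsistent pair loses both members). The
#' procedure is deterministic.
#'
#' @inheritParams rule1_shared_allele
#' @return Updated `annotation_state`.
#' @export
eliminate_inconsistencies <- function(catalog, state,
                                      config = similarity_config(),
                                      dist = NULL) {
  if (is.null(dist)) dist <- .catalog_distances(catalog)
  for (h in unique(state$assignments$allele)) {
    repeat {
      rows <- which(state$assignments$allele == h)
      if (length(rows) < 2L) break
      keys <- .motif_key(state$assignments$sample_id[rows],
                         state$assignments$motif_index[rows])
      sub <- dist[keys, keys, drop = FALSE]
      if (all(sub <= config$T)) break
      mean_d <- rowSums(sub) / (length(keys) - 1L)
      worst <- which(abs(mean_d - max(mean_d)) < 1e-12)
      state$assignments <- state$assignments[-rows[worst], , drop = FALSE]
    }
  }
  state
}

#' Fully unsupervised motif-to-allele annotation
#'
#' Applies the four co-occurrence rules in order (1, 2, 3, 4), running the
#' inconsistency elimination after each rule, and repeats the pass until a
#' full pass leaves the assignment set unchanged.
#'
#' @inheritParams rule1_shared_allele
#' @param state Optional starting `annotation_state` (e.g. carrying
#'   semi-supervised anchors); defaults to an empty state.
#' @return Final `annotation_state`.
#' @export
annotate_unsupervised <- function(catalog, config = similarity_config(),
                                  state = annotation_state(catalog)) {
  dist <- .catalog_distances(catalog)
  total_motifs <- sum(lengths(catalog))
  snapshot <- function(st) {
    a <- st$assignments
    paste(sort(paste(a$sample_id, a$motif_index, a$allele)), collapse = ";")
  }
  for (pass in seq_len(total_motifs + 2L)) {
    before <- snapshot(state)
    for (rule_fn in list(rule1_shared_allele, rule2_all_but_one,
                         rule3_last_remaining, rule4_propagate)) {
      state <- if (identical(rule_fn, rule3_last_remaining)) {
        rule_fn(catalog, state, config)
      } else {
        rule_fn(catalog, state, config, dist)
      }
      state <- eliminate_inconsistencies(catalog, state, config, dist)
    }
    if (identical(before, snapshot(state))) break
  }
  state
}

#' Semi-supervised completion against a reference motif library
#'
#' After the unsupervised pass, scans every sample for genotype alleles
#' that are still unannotated there but have a reference motif supported by
#' more than `min_ligands` ligands. If exactly one unannotated motif of
#' the sample is within the threshold of the reference PWM, it is
#' annotated to that allele. The unsupervised pass is then re-run so the
#' new anchors can unlock further co-occurrence annotations.
#'
#' @inheritParams rule1_shared_allele
#' @param state The `annotation_state` after [annotate_unsupervised()].
#' @param library A [reference_library()].
#' @param min_ligands Eligibility bound on the reference ligand count
#'   (default 20: entries need *more than* 20 ligands).
#' @return Final `annotation_state`.
#' @export
annotate_semisupervised <- function(catalog, state, library,
                                    config = similarity_config(),
                                    min_ligands = 20L) {
  genotypes <- attr(catalog, "genotypes")
  eligible <- names(library$pwms)[library$n_ligands > min_ligands]
  for (s in names(genotypes)) {
    for (h in setdiff(genotypes[[s]], .annotated_alleles_in_sample(state, s))) {
      if (!(h %in% eligible)) next
      ref <- library$pwms[[h]]
      if (nrow(ref) != attr(catalog, "length")) next
      cand <- .unannotated_motifs(catalog, state, s)
      hits <- Filter(function(m) motif_distance(m$pwm, ref) <= config$T, cand)
      if (length(hits) == 1L) {
        state <- .add_assignment(state, s, hits[[1]]$index, h, "semi")
      }
    }
  }
  state <- eliminate_inconsistencies(catalog, state, config)
  annotate_unsupervised(catalog, config, state)
}

#' Pool per-allele peptides from an annotation
#'
#' Union (deduplicated) of the hard-assigned peptides of every motif
#' annotated to each allele. Unannotated motifs contribute nowhere;
#' alleles without motifs are absent from the result.
#'
#' @param catalog A `motif_catalog`.
#' @param state A finalized `annotation_state`.
#' @return Named list: allele -> character vector of unique peptides.
#' @export
pool_allele_peptides <- function(catalog, state) {
  pools <- list()
  asn <- state$assignments
  for (i in seq_len(nrow(asn))) {
    m <- catalog[[asn$sample_id[i]]][[asn$motif_index[i]]]
    stopifnot(m$index == asn$motif_index[i])
    pools[[asn$allele[i]]] <- union(pools[[asn$allele[i]]], m$peptides)
  }
  pools
}
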