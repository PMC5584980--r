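#' Run the full motif discovery, annotation and training pipeline
#'
#' Convenience wrapper chaining the stages: per-sample two-stage
#' deconvolution ([build_motif_catalog()]), unsupervised co-occurrence
#' annotation ([annotate_unsupervised()], optionally followed by
#' [annotate_semisupervised()]), per-allele peptide pooling, MS background
#' estimation and pseudocounted per-allele model building.
#'
#' @param samples List of [sample_dataset()] objects.
#' @param length Peptide length to process (default 9).
#' @param config A [deconv_config()].
#' @param sim A [similarity_config()].
#' @param library Optional [reference_library()] enabling the
#'   semi-supervised pass.
#' @param params A [pseudocount_params()].
#' @return List with `catalog`, `state`, `pools`, `q` (MS background) and
#'   `models`.
#' @export
run_pipeline <- function(samples, length = 9L, config = deconv_config(),
                         sim = similarity_config(), library = NULL,
                         params = pseudocount_params()) {
  catalog <- build_motif_catalog(samples, length, config)
  state <- annotate_unsupervised(catalog, sim)
  if (!is.null(library)) {
    state <- annotate_semisupervised(catalog, state, library, sim)
  }
  pools <- pool_allele_peptides(catalog, state)
  # with nothing annotated (or every annotated allele excluded) there is no
  # MS pool to estimate the background from; fall back to the proteome-like
  # composition so downstream scoring still works
  q <- tryCatch(estimate_ms_background(pools), error = function(e) {
    message("MS background not estimable (", conditionMessage(e),
            "); using proteome-like frequencies")
    human_aa_frequencies()
  })
  models <- build_allele_models(pools, params, lengths = length)
  list(catalog = catalog, state = state, pools = pools, q = q,
       models = models)
}

#' Compare an annotation against a synthetic cohort's ground truth
#'
#' The true allele of a motif is the majority ground-truth label of its
#' hard-assigned peptides. An assignment is correct when the annotated
#' allele equals that majority label. An allele counts as correctly
#' annotated when it has at least one assignment and no incorrect one.
#'
#' @param cohort A `synthetic_cohort`.
#' @param catalog The `motif_catalog` deconvoluted from it.
#' @param state The final `annotation_state`.
#' @return List with `n_assignments`, `n_false`, `alleles_annotated`,
#'   `alleles_correct`, `n_alleles_truth` (alleles present in any
#'   genotype) and the per-assignment `table`.
#' @export
annotation_accuracy <- function(cohort, catalog, state) {
  labels <- cohort$labels
  labels <- labels[labels$length == attr(catalog, "length"), ]
  key <- paste(labels$sample_id, labels$peptide)
  lab_map <- stats::setNames(labels$allele, key)
  asn <- state$assignments
  truth_allele <- character(nrow(asn))
  for (i in seq_len(nrow(asn))) {
    m <- catalog[[asn$sample_id[i]]][[asn$motif_index[i]]]
    labs <- lab_map[paste(asn$sample_id[i], m$peptides)]
    tt <- sort(table(labs), decreasing = TRUE)
    truth_allele[i] <- if (length(tt)) names(tt)[1] else NA_character_
  }
  tab <- cbind(asn, truth_allele = truth_allele,
               correct = asn$allele == truth_allele)
  genotype_alleles <- unique(unlist(attr(catalog, "genotypes")))
  by_allele <- split(tab$correct, tab$allele)
  correct_alleles <- names(by_allele)[vapply(by_allele, all, logical(1))]
  list(n_assignments = nrow(tab),
       n_false = sum(!tab$correct),
       alleles_annotated = length(by_allele),
       alleles_correct = length(intersect(correct_alleles, genotype_alleles)),
       n_alleles_truth = length(genotype_alleles),
       table = tab)
}
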