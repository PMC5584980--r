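# Scripted experiments mirroring the method's computational validations at
# desk scale. Every experiment is reproducible from (design, seed) and
# returns a small report object with its config snapshot and metric table.

.experiment_report <- function(id, config, metrics, pass = NA) {
  structure(list(experiment = id, config = config, metrics = metrics,
                 pass = pass), class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Experiment:", x$experiment,
      if (!is.na(x$pass)) sprintf("(pass: %s)", x$pass), "\n")
  print(x$metrics)
  invisible(x)
}

#' Contamination robustness experiment
#'
#' Generates a clean cohort and a contaminated twin (same truth, same
#' seed, `fraction` of every sample's peptides replaced by uniform random
#' sequences), runs the full deconvolution + annotation pipeline on both,
#' and reports: whether the sample-to-allele annotation mapping is
#' unchanged, the maximum per-allele pooled-PWM entry shift, and the
#' predictor AUC on held-out ligands under both trainings.
#'
#' @param truth A `truth_spec`.
#' @param design A clean [cohort_design()] (contaminant_fraction 0).
#' @param fraction Contaminant fraction for the noisy twin (default 0.05).
#' @param config,sim Pipeline configuration.
#' @param n_test Held-out ligands per allele for the AUC probe (default 30).
#' @return An `experiment_report`; metrics: `mapping_unchanged`,
#'   `max_pwm_shift`, `auc_clean`, `auc_noisy`.
#' @export
run_noise_robustness <- function(truth, design, fraction = 0.05,
                                 config = deconv_config(),
                                 sim = similarity_config(), n_test = 30L) {
  noisy_design <- design
  noisy_design$contaminant_fraction <- fraction
  clean <- generate_cohort(truth, design)
  noisy <- generate_cohort(truth, noisy_design)
  p_clean <- run_pipeline(clean$samples, config = config, sim = sim)
  p_noisy <- run_pipeline(noisy$samples, config = config, sim = sim)

  map_of <- function(p, cohort) {
    acc <- annotation_accuracy(cohort, p$catalog, p$state)
    a <- acc$table
    sort(paste(a$sample_id, a$allele))
  }
  mapping_unchanged <- identical(map_of(p_clean, clean), map_of(p_noisy, noisy))

  shared <- intersect(names(p_clean$pools), names(p_noisy$pools))
  max_shift <- if (length(shared)) max(vapply(shared, function(a) {
    max(abs(build_reference_pwm(p_clean$pools[[a]]) -
            build_reference_pwm(p_noisy$pools[[a]])))
  }, numeric(1))) else NA_real_

  probe <- .predictor_probe(truth, p_clean, p_noisy, n_test, design$seed)

  .experiment_report(
    "noise_robustness",
    list(fraction = fraction, seed = design$seed),
    data.frame(mapping_unchanged = mapping_unchanged,
               max_pwm_shift = max_shift,
               auc_clean = probe[1], auc_noisy = probe[2]))
}

# mean per-allele AUC of both trainings on the same fresh ligands + decoys
# (each allele's held-out ligands vs its own 99-fold decoys, scored with
# that allele's model -- the mono-allelic re-prediction design)
.predictor_probe <- function(truth, p1, p2, n_test, seed) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed + 101L)
  alleles <- intersect(names(p1$models), names(p2$models))
  if (length(alleles) == 0L) return(c(NA_real_, NA_real_))
  pos <- lapply(alleles, function(a)
    sample_from_pwm(truth$pwms[[a]][["9"]], n_test))
  neg <- lapply(alleles, function(a)
    sample_from_pwm(pwm(matrix(rep(truth$background, each = 9L), nrow = 9L)),
                    99L * n_test))
  names(pos) <- names(neg) <- alleles
  vapply(list(p1, p2), function(p) {
    mean(vapply(alleles, function(a) {
      sc <- score_peptides(c(pos[[a]], neg[[a]]), p$models[[a]]$pwms[["9"]], p$q)
      evaluate_predictions(sc, c(rep(TRUE, n_test),
                                 rep(FALSE, 99L * n_test)))$auc
    }, numeric(1)))
  }, numeric(1))
}

#' Distance-threshold sweep
#'
#' Re-runs the co-occurrence annotation on one fixed motif catalog for a
#' grid of threshold values and reports, per threshold, the number of
#' annotated alleles and the fraction of same-allele motif pairs whose
#' similarity reaches empirical P < 0.05 against a reference compendium.
#'
#' @param catalog A `motif_catalog`.
#' @param T_values Thresholds to test (default `seq(0.01, 0.14, 0.01)`).
#' @param library A [reference_library()] for the P-values.
#' @return An `experiment_report`; metrics per threshold.
#' @export
run_threshold_sweep <- function(catalog,
                                T_values = seq(0.01, 0.14, by = 0.01),
                                library) {
  rows <- lapply(T_values, function(Tv) {
    sim <- similarity_config(T = Tv)
    state <- annotate_unsupervised(catalog, sim)
    frac <- same_allele_pair_significance(catalog, state, library)
    data.frame(T = Tv,
               annotated_alleles = length(unique(state$assignments$allele)),
               n_assignments = nrow(state$assignments),
               frac_pairs_significant = frac)
  })
  .experiment_report("threshold_sweep", list(T_values = T_values),
                     do.call(rbind, rows))
}

#' Fraction of same-allele motif pairs with significant similarity
#'
#' For every allele with at least two annotated motifs, computes the
#' empirical similarity P-value of each ordered motif pair against the
#' reference library (excluding the allele itself) and returns the
#' fraction below `alpha`.
#'
#' @param catalog A `motif_catalog`.
#' @param state An `annotation_state`.
#' @param library A [reference_library()].
#' @param sim A [similarity_config()].
#' @param alpha Significance level (default 0.05).
#' @return Fraction in [0, 1], or `NA` if no allele has two motifs.
#' @export
same_allele_pair_significance <- function(catalog, state, library,
                                          sim = similarity_config(),
                                          alpha = 0.05) {
  asn <- state$assignments
  ps <- c()
  for (h in unique(asn$allele)) {
    rows <- which(asn$allele == h)
    if (length(rows) < 2L) next
    pwms <- lapply(rows, function(i)
      catalog[[asn$sample_id[i]]][[asn$motif_index[i]]]$pwm)
    for (i in seq_along(rows)) for (j in seq_along(rows)) {
      if (i == j) next
      ps <- c(ps, empirical_similarity_pvalue(pwms[[i]], pwms[[j]], library,
                                              exclude = h, config = sim))
    }
  }
  if (length(ps) == 0L) return(NA_real_)
  mean(ps < alpha)
}

#' Sub-sampling convergence of pooled motifs
#'
#' For increasing numbers of pooled samples, measures the squared
#' Euclidean distance between each allele's pooled motif (flat +1-count
#' PWM over the peptides annotated to it in the first `m` carrying
#' samples) and the allele's truth PWM, averaged over alleles and
#' replicate cohorts.
#'
#' @param truth A `truth_spec`.
#' @param design A [cohort_design()].
#' @param sample_counts Numbers of samples to pool (default `c(1, 2, 4)`).
#' @param n_seeds Replicate cohorts (default 10).
#' @param config,sim Pipeline configuration.
#' @return An `experiment_report`; metrics: one row per `sample_count`
#'   with the mean D^2 to truth.
#' @export
run_subsample_convergence <- function(truth, design,
                                      sample_counts = c(1, 2, 4),
                                      n_seeds = 10L,
                                      config = deconv_config(),
                                      sim = similarity_config()) {
  per_seed <- lapply(seq_len(n_seeds), function(s) {
    d <- design
    d$seed <- design$seed + s
    cohort <- generate_cohort(truth, d)
    cfg <- config
    cfg$seed <- config$seed + s
    p <- run_pipeline(cohort$samples, config = cfg, sim = sim)
    asn <- p$state$assignments
    vapply(sample_counts, function(m) {
      ds <- c()
      for (h in unique(asn$allele)) {
        rows <- which(asn$allele == h)
        rows <- rows[order(asn$sample_id[rows])][seq_len(min(m, length(rows)))]
        peps <- unique(unlist(lapply(rows, function(i)
          p$catalog[[asn$sample_id[i]]][[asn$motif_index[i]]]$peptides)))
        if (length(peps) == 0L || !(h %in% names(truth$pwms))) next
        pooled <- build_reference_pwm(peps)
        ds <- c(ds, motif_distance(pooled, truth$pwms[[h]][["9"]]))
      }
      mean(ds)
    }, numeric(1))
  })
  mat <- do.call(rbind, per_seed)
  .experiment_report(
    "subsample_convergence",
    list(sample_counts = sample_counts, n_seeds = n_seeds,
         seed = design$seed),
    data.frame(sample_count = sample_counts, mean_d2 = colMeans(mat)))
}

#' Leave-one-sample-out neo-antigen validation
#'
#' Plants a neo-antigen for an allele carried by the held-out sample,
#' ranks the candidate list with models trained on the full cohort and
#' with models retrained without the held-out sample's peptidome, and
#' reports both ranks.
#'
#' @param truth A `truth_spec`.
#' @param design A [cohort_design()].
#' @param held_out Sample id to exclude from the retraining.
#' @param allele Allele of the planted neo-antigen (must be carried by
#'   `held_out` and by at least one other sample).
#' @param n_mutations Random missense mutations forming the candidate
#'   background (default 50).
#' @param config,sim Pipeline configuration.
#' @return An `experiment_report`; metrics: planted peptide, rank with
#'   full and with reduced training, candidate count.
#' @export
run_leave_one_sample_out <- function(truth, design, held_out, allele,
                                     n_mutations = 50L,
                                     config = deconv_config(),
                                     sim = similarity_config()) {
  cohort <- generate_cohort(truth, design)
  stopifnot(held_out %in% names(cohort$samples))
  pm <- generate_proteome_and_mutations(
    n_proteins = 50L, protein_length = 500L, n_mutations = n_mutations,
    seed = design$seed + 17L, plant = list(truth = truth, allele = allele))

  # the candidate ranking uses only the alleles present in the evaluated
  # patient's genotype, as in per-patient neo-antigen prioritization
  genotype <- validate_genotype(strsplit(
    design$samples$alleles[design$samples$sample_id == held_out], ",")[[1]])
  rank_of <- function(samples) {
    p <- run_pipeline(samples, config = config, sim = sim)
    models <- p$models[intersect(genotype, names(p$models))]
    bg <- score_background(models, p$q, pm$proteome, n = 20000L,
                           seed = design$seed, lengths = c(9L))
    pred <- rank_neoantigens(pm$mutations, models, p$q, bg,
                             proteome = pm$proteome, lengths = 9L)
    list(rank = pred$rank[pred$peptide == pm$planted$peptide],
         n = nrow(pred))
  }
  full <- rank_of(cohort$samples)
  reduced <- rank_of(cohort$samples[setdiff(names(cohort$samples), held_out)])
  .experiment_report(
    "leave_one_sample_out",
    list(held_out = held_out, allele = allele, seed = design$seed),
    data.frame(peptide = pm$planted$peptide,
               rank_full = full$rank, rank_heldout = reduced$rank,
               n_candidates = full$n))
}
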