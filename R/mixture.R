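#' EM configuration for motif deconvolution
#'
#' Hyper-parameters of the mixture-of-PWMs EM fit.
#'
#' @param seed Integer seed for the random restarts.
#' @param n_restarts Number of random initializations (default 5).
#' @param max_iter Maximum EM iterations per run (default 500).
#' @param rel_tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param gamma Dirichlet smoothing count added per residue per position in
#'   the M-step (default 0.1); keeps emission probabilities strictly
#'   positive. Distinct from the predictor's BLOSUM pseudocounts, which are
#'   applied only to final per-allele PWMs.
#' @param burn_iter EM iterations given to every restart before the single
#'   best restart (by log-likelihood) is run to convergence (default 15).
#'   Set to `max_iter` to run every restart fully.
#' @param background_component Include a flat background ("trash")
#'   component -- fixed uniform emissions, free mixing weight -- in the
#'   per-sample deconvolution (default TRUE). MS contaminant peptides match
#'   no allele motif and would otherwise be absorbed into motif clusters
#'   and distort their anchor probabilities.
#' @return A list of class `deconv_config`.
#' @export
deconv_config <- function(seed = 1L, n_restarts = 5L, max_iter = 500L,
                          rel_tol = 1e-6, gamma = 0.1, burn_iter = 15L,
                          background_component = TRUE) {
  stopifnot(n_restarts >= 1, max_iter >= 1, rel_tol > 0, rel_tol < 1,
            gamma >= 0, burn_iter >= 1, is.logical(background_component))
  structure(list(seed = as.integer(seed), n_restarts = as.integer(n_restarts),
                 max_iter = as.integer(max_iter), rel_tol = rel_tol,
                 gamma = gamma, burn_iter = as.integer(burn_iter),
                 background_component = isTRUE(background_component)),
            class = "deconv_config")
}

# one seeded Dirichlet(1) responsibility initialization
.init_responsibilities <- function(n, K) {
  g <- matrix(stats::rexp(n * K), nrow = n, ncol = K)
  g / rowSums(g)
}

#' Fit a mixture of PWMs to a single-length peptide list
#'
#' Runs EM for a `K`-component mixture of position-independent PWMs.
#' E-step: responsibilities proportional to the mixing weight times the
#' product of PWM entries along the peptide. M-step: responsibility-weighted
#' residue counts with `gamma` Dirichlet smoothing, weights set to the mean
#' responsibilities. The best of `n_restarts` seeded random initializations
#' (by final log-likelihood) is returned.
#'
#' @param peptides Character vector of equal-length peptides.
#' @param K Number of motifs (components), `1 <= K <= length(peptides)`.
#' @param config A [deconv_config()].
#' @param trash Add a flat background component with fixed uniform
#'   emissions alongside the `K` motif components (default FALSE; the
#'   sample deconvolution pipeline turns it on via
#'   `config$background_component`). Its responsibilities appear as column
#'   `K + 1`.
#' @return An object of class `pep_mixture`: list with `K`, `pwms` (list of
#'   [pwm()]), `weights` (length `K` or `K + 1` with a trash component),
#'   `responsibilities` (n x K, or n x (K+1)), `log_likelihood`,
#'   `ll_trace`, `n`, `L`, `peptides`, `trash`, `bic`.
#' @export
fit_mixture <- function(peptides, K, config = deconv_config(),
                        trash = FALSE) {
  if (K < 1L) stop("K must be >= 1")
  n <- length(peptides)
  if (n < K) stop("need at least K peptides (n = ", n, ", K = ", K, ")")
  idx <- encode_peptides(peptides)
  L <- ncol(idx)
  n_comp <- K + as.integer(trash)

  run_em <- function(r0, iters) {
    .em_fit_cpp(idx, r0, config$gamma, iters, config$rel_tol, trash)
  }

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed + 7919L * K)

  inits <- replicate(config$n_restarts, .init_responsibilities(n, n_comp),
                     simplify = FALSE)
  if (n_comp == 1L) inits <- inits[1]  # closed form, restarts are identical

  burn <- min(config$burn_iter, config$max_iter)
  runs <- lapply(inits, run_em, iters = burn)
  best <- which.max(vapply(runs, `[[`, numeric(1), "log_likelihood"))
  fit <- runs[[best]]
  if (burn < config$max_iter) {
    fit2 <- run_em(fit$responsibilities, config$max_iter)
    fit2$ll_trace <- c(fit$ll_trace, fit2$ll_trace)
    fit <- fit2
  }

  nu <- (n_comp - 1) + K * L * 19     # free parameters
  structure(list(
    K = K,
    pwms = lapply(fit$pwms, pwm),
    weights = as.numeric(fit$weights),
    responsibilities = fit$responsibilities,
    log_likelihood = fit$log_likelihood,
    ll_trace = fit$ll_trace,
    n = n, L = L,
    peptides = peptides,
    trash = isTRUE(trash),
    bic = -2 * fit$log_likelihood + nu * log(n)
  ), class = "pep_mixture")
}

#' @export
print.pep_mixture <- function(x, ...) {
  cat(sprintf("PWM mixture: K = %d motifs, n = %d %d-mers, logL = %.2f, BIC = %.1f\n",
              x$K, x$n, x$L, x$log_likelihood, x$bic))
  cat("weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  invisible(x)
}

#' Select the number of motifs by BIC
#'
#' Fits mixtures for `K = 1..K_max` and returns the model minimizing
#' `BIC = -2 logL + nu log(n)` with `nu = K - 1 + K * L * 19` free
#' parameters. All candidate BICs are attached as attribute `bic_table`.
#'
#' @inheritParams fit_mixture
#' @param K_max Largest number of motifs to consider.
#' @return The selected `pep_mixture`, with a `bic_table` data frame
#'   (columns `K`, `log_likelihood`, `bic`) as an attribute.
#' @export
select_num_motifs <- function(peptides, K_max, config = deconv_config(),
                              trash = FALSE) {
  stopifnot(K_max >= 1)
  K_max <- min(K_max, length(peptides))
  fits <- lapply(seq_len(K_max),
                 function(K) fit_mixture(peptides, K, config, trash = trash))
  tab <- data.frame(K = seq_len(K_max),
                    log_likelihood = vapply(fits, `[[`, numeric(1), "log_likelihood"),
                    bic = vapply(fits, `[[`, numeric(1), "bic"))
  best <- fits[[which.min(tab$bic)]]
  attr(best, "bic_table") <- tab
  best
}

#' Hard-assign peptides to motifs
#'
#' Maps each peptide to the motif with the highest responsibility; ties are
#' broken towards the lowest motif index. With a background component,
#' peptides whose highest responsibility falls on it get motif `NA`
#' (treated as contaminants, they belong to no motif).
#'
#' @param model A fitted `pep_mixture`.
#' @return Data frame with columns `peptide` and `motif` (1-based index or
#'   `NA` for background).
#' @export
assign_peptides <- function(model) {
  stopifnot(inherits(model, "pep_mixture"))
  motif <- max.col(model$responsibilities, ties.method = "first")
  if (isTRUE(model$trash)) motif[motif > model$K] <- NA_integer_
  data.frame(peptide = model$peptides, motif = motif,
             stringsAsFactors = FALSE)
}

#' Two-stage deconvolution of one sample
#'
#' Stage 1 fits a mixture with the number of motifs fixed to the number of
#' distinct HLA-A plus HLA-B alleles in the genotype (these loci are more
#' highly expressed and dominate the peptidome signal). Stage 2 re-fits
#' with the number of motifs selected by BIC over `K = 1..(genotype size
#' + 1)`, the extra component leaving room for contaminants.
#'
#' @param sample A [sample_dataset()].
#' @param length Peptide length to deconvolute (9 or 10).
#' @param config A [deconv_config()].
#' @return List with elements `stage1` and `stage2` (both `pep_mixture`,
#'   `stage1` is `NULL` when the genotype has no A/B alleles) and their
#'   hard `assignments`.
#' @export
deconvolve_sample <- function(sample, length = 9L, config = deconv_config()) {
  stopifnot(inherits(sample, "sample_dataset"))
  if (base::length(sample$genotype) == 0L) stop("sample has an empty genotype")
  peptides <- sample$peptides_by_length[[as.character(length)]]
  if (is.null(peptides) || base::length(peptides) == 0L) {
    stop("sample ", sample$sample_id, " has no ", length, "-mers")
  }
  k1 <- sum(allele_locus(sample$genotype) %in% c("A", "B"))
  trash <- isTRUE(config$background_component)
  stage1 <- if (k1 >= 1L) fit_mixture(peptides, k1, config, trash = trash) else NULL
  stage2 <- select_num_motifs(peptides, base::length(sample$genotype) + 1L,
                              config, trash = trash)
  list(stage1 = stage1, stage2 = stage2,
       assignments = assign_peptides(stage2))
}
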