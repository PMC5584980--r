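test_that("the MS background averages allele frequency vectors at P4-P7", {
  # identical pools -> q equals the shared vector
  pool <- rep("AAALLLLKK", 40)                    # P4-P7 = LLLL
  pools <- list(B0101 = pool, B0201 = pool)
  q <- estimate_ms_background(pools, excluded = character(0))
  expect_gt(q["L"], 0.99)

  # two alleles -> unweighted mean of their vectors
  pools2 <- list(B0101 = rep("AAALLLLKK", 10), B0201 = rep("AAAGGGGKK", 30))
  q2 <- estimate_ms_background(pools2, excluded = character(0))
  expect_equal(unname(q2["L"]), unname(q2["G"]), tolerance = 1e-6)

  # excluded alleles are ignored in the average
  pools3 <- c(pools2, list(A0201 = rep("AAAWWWWKK", 10)))
  q3 <- estimate_ms_background(pools3)            # A0201 is on the default list
  expect_equal(q3, q2, tolerance = 1e-9)
  expect_error(estimate_ms_background(pools3["A0201"]), "no non-excluded")

  # floored entries keep the vector strictly positive and normalized
  expect_true(all(q2 > 0))
  expect_equal(sum(q2), 1, tolerance = 1e-9)
})

test_that("proteome frequencies and Pearson correlation behave as stated", {
  prot <- c(p1 = "AAAC", p2 = "CCDD")
  f <- proteome_frequencies(prot)
  expect_equal(unname(f[c("A", "C", "D")]), c(3, 3, 2) / 8)

  q1 <- human_aa_frequencies()
  expect_equal(pearson_r(q1, q1), 1)
  expect_equal(pearson_r(q1, 2 * q1 + 0.01), 1)   # affine invariance
  expect_error(pearson_r(rep(0.05, 20), q1), "zero-variance")

  # cysteine depletion lowers but does not destroy the correlation
  dep <- q1; dep["C"] <- dep["C"] / 5; dep <- dep / sum(dep)
  r <- pearson_r(dep, q1)
  expect_lt(r, 1)
  expect_gt(r, 0.8)
  r_oracle <- sum((dep - mean(dep)) * (q1 - mean(q1))) /
    sqrt(sum((dep - mean(dep))^2) * sum((q1 - mean(q1))^2))
  expect_equal(r, r_oracle, tolerance = 1e-12)
})

test_that("BLOSUM62 pseudocount PWMs interpolate between data and prior", {
  rho <- blosum62_conditional()
  expect_equal(rowSums(rho), setNames(rep(1, 20), aa_alphabet()),
               tolerance = 1e-9)
  # conservation dominates: each residue's most likely "substitution" is
  # itself, and rare residues (W, C) are the most conserved
  expect_identical(unname(apply(rho, 1, which.max)),
                   match(aa_alphabet(), aa_alphabet()))
  expect_true(all(diag(rho) > 1 / 20))
  expect_gt(rho["W", "W"], rho["A", "A"])

  params <- pseudocount_params()                  # beta = 200
  set.seed(1)
  peps <- sample_from_pwm(random_pwm(9), 201)     # alpha = n - 1 = 200 = beta
  p <- build_allele_pwm(peps, params)
  cm <- count_matrix(peps)
  f <- cm / rowSums(cm)
  g <- f %*% rho
  expect_lt(max(abs(unclass(p) - (f + g) / 2)), 1e-12)

  # n = 1: alpha = 0, pure pseudocounts
  p1 <- build_allele_pwm("AAAAAAAAA", params)
  expect_equal(unname(unclass(p1)[1, ]), unname(rho["A", ]), tolerance = 1e-12)

  # n large with a constant column: data dominates
  pbig <- build_allele_pwm(rep("AAAAAAAAA", 20001), params)
  f_dom <- (20000 * 1 + 200 * rho["A", "A"]) / 20200
  expect_equal(unname(pbig[1, "A"]), unname(f_dom), tolerance = 1e-9)
  expect_gt(pbig[1, "A"], 0.98)

  expect_error(build_allele_pwm(c("AAAA", "AAAAA")), "same length")
})

test_that("peptide scores decompose into per-position log ratios", {
  q <- setNames(rep(0.05, 20), aa_alphabet())
  u <- uniform_pwm(9)
  expect_equal(score_peptides("ACDEFGHIK", u, q), 0)

  # p = 2q everywhere -> S = ln 2
  p2 <- pwm(matrix(rep(c(0.1, rep(0.9 / 19, 19)), 9), nrow = 9, byrow = TRUE))
  expect_equal(score_peptides("AAAAAAAAA", p2, q), log(2), tolerance = 1e-12)

  # ratio 4 at P1 only -> S = ln(4) / 9
  m <- unclass(uniform_pwm(9))
  m[1, ] <- c(0.2, rep(0.8 / 19, 19))
  expect_equal(score_peptides("AAAAAAAAA", pwm(m), q), log(4) / 9,
               tolerance = 1e-12)

  # independent per-position oracle on random inputs
  set.seed(2)
  p <- random_pwm(9)
  qh <- human_aa_frequencies()
  peps <- sample_from_pwm(p, 20)
  s <- score_peptides(peps, p, qh)
  oracle <- vapply(peps, function(x) {
    acc <- 0
    for (i in 1:9) {
      a <- substr(x, i, i)
      acc <- acc + log(p[i, a] / qh[a])
    }
    acc / 9
  }, numeric(1))
  expect_lt(max(abs(s - unname(oracle))), 1e-10)

  expect_error(score_peptides("AAAA", p, qh), "does not match")
})

test_that("prediction takes the max over alleles and calibrated P-values", {
  q <- human_aa_frequencies()
  tr <- generate_truth(2, seed = 3, loci = c("A", "B"))
  pools <- lapply(tr$alleles, function(a) sample_from_pwm(tr$pwms[[a]][["9"]], 300))
  names(pools) <- tr$alleles
  models <- build_allele_models(pools)
  prot <- generate_proteome_and_mutations(20, 400, 0, seed = 4)$proteome
  bg <- score_background(models, q, prot, n = 5000, seed = 5)

  lig <- sample_from_pwm(tr$pwms[[1]][["9"]], 20)
  pred <- predict_peptides(lig, models, q, bg)
  expect_true(all(pred$best_allele == tr$alleles[1]) || mean(pred$best_allele == tr$alleles[1]) > 0.9)
  expect_true(all(pred$p_value > 0 & pred$p_value <= 1))
  # a score above every background value gets the add-one floor
  top <- pred$score[1]
  expect_equal(pred$p_value[1], (1 + sum(bg[["9"]] >= top)) / (1 + 5000))

  # single-allele model set: every best_allele is that allele
  pred1 <- predict_peptides(lig, models[1], q, bg_one <- score_background(
    models[1], q, prot, n = 1000, seed = 6))
  expect_true(all(pred1$best_allele == tr$alleles[1]))

  # deterministic lexicographic tie-break in the ranking
  same <- c("AAAAAAAAC", "AAAAAAAAA")
  m_flat <- list(A0101 = structure(
    list(allele = "A0101", pwms = list(`9` = uniform_pwm(9)), n = c(`9` = 10L)),
    class = "allele_model"))
  qz <- setNames(rep(0.05, 20), aa_alphabet())
  pr <- predict_peptides(same, m_flat, qz, list(`9` = sort(rnorm(100))))
  expect_identical(pr$score[1], pr$score[2])
  expect_identical(pr$peptide, sort(same))
})

test_that("missense candidate enumeration counts windows exactly", {
  prot <- paste(rep("A", 100), collapse = "")
  mk <- function(pos, alt = "L") data.frame(
    protein_id = "p", sequence = prot, position = pos, ref = "A", alt = alt,
    stringsAsFactors = FALSE)
  expect_length(enumerate_missense_candidates(mk(50)), 19)  # 9 + 10
  expect_length(enumerate_missense_candidates(mk(3)), 6)    # 3 + 3
  expect_length(enumerate_missense_candidates(mk(100)), 2)  # 1 + 1
  expect_length(enumerate_missense_candidates(mk(1)), 2)

  # duplicate candidates across records are merged
  two <- rbind(mk(50), mk(50))
  expect_length(enumerate_missense_candidates(two), 19)

  # invariant violations are rejected
  expect_error(enumerate_missense_candidates(mk(50, alt = "A")), "identical")
  bad <- mk(50); bad$ref <- "C"
  expect_error(enumerate_missense_candidates(bad), "mismatch")

  # a protein shorter than the window yields nothing for that length
  short <- data.frame(protein_id = "s", sequence = "AAAAAAAA", position = 4,
                      ref = "A", alt = "L", stringsAsFactors = FALSE)
  expect_length(enumerate_missense_candidates(short), 0)
})

test_that("benchmark metrics match their definitions", {
  # perfect separation with 1% positives at 99-fold decoys
  scores <- c(rep(10, 10), rnorm(990))
  labs <- c(rep(TRUE, 10), rep(FALSE, 990))
  ev <- evaluate_predictions(scores, labs)
  expect_equal(ev$auc, 1)
  expect_equal(ev$pp1, 1)

  # worked case: 100 positives, 9900 decoys, 80 in the top 100
  sc <- c(seq(200, 101), seq(-1, -9900))          # positives at ranks 1..100
  lb <- c(rep(TRUE, 80), rep(FALSE, 20), rep(TRUE, 20), rep(FALSE, 9880))
  expect_equal(evaluate_predictions(sc, lb)$pp1, 0.80)

  # random scores: AUC ~ 0.5, checked against an independent implementation
  set.seed(7)
  rsc <- rnorm(10000); rlb <- rep(c(TRUE, FALSE), 5000)
  ev2 <- evaluate_predictions(rsc, rlb)
  expect_equal(ev2$auc, 0.5, tolerance = 0.02)
  skip_if_not_installed("pROC")
  auc_ref <- as.numeric(pROC::auc(pROC::roc(rlb, rsc, quiet = TRUE,
                                            direction = "<")))
  expect_equal(ev2$auc, auc_ref, tolerance = 1e-12)

  expect_error(evaluate_predictions(rsc, rep(TRUE, 10000)), "at least one")
})

test_that("tryptic-signature filtering respects the exception alleles", {
  peps <- c("AAAAAAAAK", "AAAAAAAAL", "AAAAAAAAR")
  expect_identical(filter_tryptic_signature(peps, "B0702"), "AAAAAAAAL")
  expect_identical(filter_tryptic_signature(peps, "A0301"), peps)
  expect_identical(filter_tryptic_signature(peps, "HLA-A31:01"), peps)
  expect_identical(filter_tryptic_signature(character(0), "B0702"),
                   character(0))
})
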