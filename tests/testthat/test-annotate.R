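# Toy catalogs built from explicit PWMs exercise each co-occurrence rule in
# isolation; cohort-level behaviour is covered in test-acceptance.R.

motifs <- list(
  X = anchored_pwm(9, "L", "V"),
  Y = anchored_pwm(9, "E", "K"),
  Z = anchored_pwm(9, "Y", "F"),
  W = anchored_pwm(9, "S", "I")
)
jitter_pwm <- function(p, eps = 0.005, seed = 1) {
  set.seed(seed)
  m <- unclass(p) + matrix(runif(length(p), 0, eps), nrow = nrow(p))
  pwm(m / rowSums(m))
}

test_that("rule 1 annotates the unique shared motif across sharing samples", {
  cat3 <- toy_catalog(
    list(s1 = list(motifs$X, motifs$Y),
         s2 = list(jitter_pwm(motifs$X, seed = 2), motifs$Z),
         s3 = list(motifs$W, jitter_pwm(motifs$X, seed = 3))),
    genotypes = list(s1 = c("A0101", "B0101"),
                     s2 = c("A0101", "B0201"),
                     s3 = c("A0101", "B0301")))
  st <- rule1_shared_allele(cat3, annotation_state(cat3))
  got <- st$assignments[st$assignments$allele == "A0101", ]
  expect_identical(nrow(got), 3L)
  expect_setequal(paste(got$sample_id, got$motif_index),
                  c("s1 1", "s2 1", "s3 2"))

  # negative case: no cross-sample pair within T -> nothing happens
  cat_neg <- toy_catalog(
    list(s1 = list(motifs$X), s2 = list(motifs$Y)),
    genotypes = list(s1 = "A0101", s2 = "A0101"))
  expect_identical(nrow(rule1_shared_allele(
    cat_neg, annotation_state(cat_neg))$assignments), 0L)
})

test_that("rule 1 defers when two mutually consistent cliques exist", {
  # s1 and s2 share both A0101 and B0101 and both motif pairs match:
  # the clique is not unique, so nothing may be annotated yet
  cat_amb <- toy_catalog(
    list(s1 = list(motifs$X, motifs$Y),
         s2 = list(jitter_pwm(motifs$X, seed = 4), jitter_pwm(motifs$Y, seed = 5))),
    genotypes = list(s1 = c("A0101", "B0101"), s2 = c("A0101", "B0101")))
  st <- rule1_shared_allele(cat_amb, annotation_state(cat_amb))
  expect_identical(nrow(st$assignments), 0L)
  # oracle: exhaustive clique enumeration on the 2x2 instance
  d <- HLAdecon:::.catalog_distances(cat_amb)
  Tv <- similarity_config()$T
  cliques <- 0
  for (i in 1:2) for (j in 1:2) {
    if (d[paste0("s1|", i), paste0("s2|", j)] <= Tv) cliques <- cliques + 1
  }
  expect_identical(cliques, 2)
})

test_that("rule 2 maps the unshared motif to the unshared allele", {
  cat2 <- toy_catalog(
    list(A = list(motifs$X, motifs$Y, motifs$Z),
         B = list(jitter_pwm(motifs$X, seed = 6), jitter_pwm(motifs$Y, seed = 7))),
    genotypes = list(A = c("A0101", "B0101", "C0101"),
                     B = c("A0101", "B0101")))
  st <- rule2_all_but_one(cat2, annotation_state(cat2))
  expect_identical(st$assignments$allele, "C0101")
  expect_identical(st$assignments$sample_id, "A")
  expect_identical(st$assignments$motif_index, 3L)
  expect_identical(st$assignments$rule, "2")

  # ambiguity guard: two unmatched motifs -> no annotation
  cat2b <- toy_catalog(
    list(A = list(motifs$X, motifs$Y, motifs$Z),
         B = list(jitter_pwm(motifs$X, seed = 8))),
    genotypes = list(A = c("A0101", "B0101", "C0101"),
                     B = c("A0101")))
  # A \ B = {B0101, C0101}: two extra alleles, rule 2 does not apply
  expect_identical(nrow(rule2_all_but_one(
    cat2b, annotation_state(cat2b))$assignments), 0L)
})

test_that("rule 2 adds a consistent annotation for an allele known elsewhere", {
  catx <- toy_catalog(
    list(A = list(motifs$X, motifs$Z),
         B = list(jitter_pwm(motifs$X, seed = 9)),
         C = list(jitter_pwm(motifs$Z, seed = 10))),
    genotypes = list(A = c("A0101", "C0101"), B = "A0101", C = "C0101"))
  st <- annotation_state(catx)
  st <- HLAdecon:::.add_assignment(st, "C", 1L, "C0101", "manual")
  st <- rule2_all_but_one(catx, st)
  new <- st$assignments[st$assignments$rule == "2" &
                          st$assignments$allele == "C0101", ]
  expect_identical(nrow(new), 1L)
  expect_identical(new$sample_id, "A")
  expect_identical(new$motif_index, 2L)
  # consistency oracle: the new motif is within T of the existing one
  d <- HLAdecon:::.catalog_distances(catx)
  expect_lte(d["A|2", "C|1"], similarity_config()$T)
  st2 <- eliminate_inconsistencies(catx, st)
  expect_identical(nrow(st2$assignments), nrow(st$assignments))
})

test_that("rule 3 matches the last motif to the last allele", {
  cat3 <- toy_catalog(
    list(s = list(motifs$X, motifs$Y, motifs$Z, motifs$W)),
    genotypes = list(s = c("A0101", "A0201", "B0101", "B0201")))
  st <- annotation_state(cat3)
  for (i in 1:3) {
    st <- HLAdecon:::.add_assignment(st, "s", i,
                                     c("A0101", "A0201", "B0101")[i], "manual")
  }
  st <- rule3_last_remaining(cat3, st)
  expect_identical(st$assignments$allele[4], "B0201")
  expect_identical(st$assignments$motif_index[4], 4L)

  # two unannotated motifs, one unannotated allele -> no-op
  st2 <- annotation_state(cat3)
  st2 <- HLAdecon:::.add_assignment(st2, "s", 1L, "A0101", "manual")
  st2 <- HLAdecon:::.add_assignment(st2, "s", 2L, "A0201", "manual")
  st2 <- HLAdecon:::.add_assignment(st2, "s", 3L, "B0101", "manual")
  st2$assignments <- st2$assignments[1:2, ]       # 2 motifs, 2 alleles left
  expect_identical(nrow(rule3_last_remaining(cat3, st2)$assignments), 2L)
})

test_that("rule 4 propagates an annotated motif when exactly one candidate fits", {
  cat4 <- toy_catalog(
    list(s1 = list(motifs$X), s2 = list(jitter_pwm(motifs$X, seed = 11)),
         s3 = list(jitter_pwm(motifs$X, seed = 12), motifs$Y)),
    genotypes = list(s1 = "A0101", s2 = "A0101", s3 = c("A0101", "B0101")))
  st <- annotation_state(cat4)
  st <- HLAdecon:::.add_assignment(st, "s1", 1L, "A0101", "1")
  st <- HLAdecon:::.add_assignment(st, "s2", 1L, "A0101", "1")
  st <- rule4_propagate(cat4, st)
  new <- st$assignments[st$assignments$rule == "4", ]
  expect_identical(paste(new$sample_id, new$motif_index, new$allele),
                   "s3 1 A0101")

  # two candidates within T -> ambiguity guard
  cat4b <- toy_catalog(
    list(s1 = list(motifs$X),
         s3 = list(jitter_pwm(motifs$X, seed = 13),
                   jitter_pwm(motifs$X, seed = 14))),
    genotypes = list(s1 = "A0101", s3 = c("A0101", "B0101")))
  stb <- HLAdecon:::.add_assignment(annotation_state(cat4b), "s1", 1L, "A0101", "1")
  expect_identical(nrow(rule4_propagate(cat4b, stb)$assignments), 1L)

  # candidate close to one anchor motif but far from another -> no-op
  cat4c <- toy_catalog(
    list(s1 = list(motifs$X), s2 = list(motifs$Y),
         s3 = list(jitter_pwm(motifs$X, seed = 15))),
    genotypes = list(s1 = "A0101", s2 = "A0101", s3 = "A0101"))
  stc <- annotation_state(cat4c)
  stc <- HLAdecon:::.add_assignment(stc, "s1", 1L, "A0101", "1")
  stc <- HLAdecon:::.add_assignment(stc, "s2", 1L, "A0101", "1")
  d <- HLAdecon:::.catalog_distances(cat4c)
  expect_lte(d["s3|1", "s1|1"], 0.078)
  expect_gt(d["s3|1", "s2|1"], 0.078)
  expect_identical(nrow(rule4_propagate(cat4c, stc)$assignments), 2L)
})

test_that("inconsistency elimination removes worst-mean-distance motifs", {
  cat5 <- toy_catalog(
    list(s1 = list(motifs$X), s2 = list(jitter_pwm(motifs$X, seed = 16)),
         s3 = list(motifs$Y)),
    genotypes = list(s1 = "A0101", s2 = "A0101", s3 = "A0101"))
  st <- annotation_state(cat5)
  for (s in c("s1", "s2", "s3")) st <- HLAdecon:::.add_assignment(st, s, 1L, "A0101", "1")
  st2 <- eliminate_inconsistencies(cat5, st)
  expect_identical(sort(st2$assignments$sample_id), c("s1", "s2"))
  # oracle: s3's motif has the largest mean distance to the others
  d <- HLAdecon:::.catalog_distances(cat5)
  means <- sapply(c("s1|1", "s2|1", "s3|1"), function(k)
    mean(d[k, setdiff(c("s1|1", "s2|1", "s3|1"), k)]))
  expect_identical(names(which.max(means)), "s3|1")

  # consistent state is a fixed point
  st3 <- eliminate_inconsistencies(cat5, st2)
  expect_identical(st3$assignments, st2$assignments)

  # mutually inconsistent pair: tie on mean distance -> both removed
  cat6 <- toy_catalog(
    list(s1 = list(motifs$X), s2 = list(motifs$Y)),
    genotypes = list(s1 = "A0101", s2 = "A0101"))
  st4 <- annotation_state(cat6)
  st4 <- HLAdecon:::.add_assignment(st4, "s1", 1L, "A0101", "1")
  st4 <- HLAdecon:::.add_assignment(st4, "s2", 1L, "A0101", "1")
  expect_identical(nrow(eliminate_inconsistencies(cat6, st4)$assignments), 0L)
})

test_that("the recursive pass reproduces the three-sample worked topology", {
  # one allele in all three samples, two alleles each shared by two; the
  # remaining alleles are private and stay unannotated
  cat7 <- toy_catalog(
    list(s1 = list(motifs$X, motifs$Y, random_pwm(9)),
         s2 = list(jitter_pwm(motifs$X, seed = 17), jitter_pwm(motifs$Y, seed = 18),
                   motifs$Z),
         s3 = list(jitter_pwm(motifs$X, seed = 19), jitter_pwm(motifs$Z, seed = 20),
                   motifs$W)),
    genotypes = list(s1 = c("A2402", "A0101", "B0101", "C0702"),
                     s2 = c("A2402", "A0101", "C0602", "B0702"),
                     s3 = c("A2402", "C0602", "B0301", "A2902")))
  st <- annotate_unsupervised(cat7)
  by_allele <- split(paste(st$assignments$sample_id, st$assignments$motif_index),
                     st$assignments$allele)
  expect_setequal(by_allele$A2402, c("s1 1", "s2 1", "s3 1"))
  expect_setequal(by_allele$A0101, c("s1 2", "s2 2"))
  expect_setequal(by_allele$C0602, c("s2 3", "s3 2"))
  # private alleles remain unannotated (their motifs match nothing)
  expect_false("B0101" %in% st$assignments$allele)

  # a single-sample cohort can never fire a rule
  cat1 <- toy_catalog(list(solo = list(motifs$X, motifs$Y)),
                      genotypes = list(solo = c("A0101", "B0101")))
  expect_identical(nrow(annotate_unsupervised(cat1)$assignments), 0L)
})

test_that("sample order does not change the final annotation", {
  # compact fully rule-1-identifiable design: 4 samples, 6 alleles
  tr <- generate_truth(6, seed = 31, loci = c("A", "A", "B", "B", "C", "C"))
  des <- cohort_design(
    data.frame(sample_id = paste0("M", 1:4),
               alleles = c("A0101,B0101,C0101", "A0101,B0201,C0201",
                           "A0201,B0101,C0201", "A0201,B0201,C0101")),
    peptides_per_sample = 2000, seed = 31)
  cohort <- generate_cohort(tr, des)
  cfg <- deconv_config(seed = 31)
  cat_f <- build_motif_catalog(cohort$samples, 9, cfg)
  cat_r <- build_motif_catalog(rev(cohort$samples), 9, cfg)
  st_f <- annotate_unsupervised(cat_f)
  st_r <- annotate_unsupervised(cat_r)
  pool_f <- pool_allele_peptides(cat_f, st_f)
  pool_r <- pool_allele_peptides(cat_r, st_r)
  expect_setequal(names(pool_f), names(pool_r))
  for (a in names(pool_f)) expect_setequal(pool_f[[a]], pool_r[[a]])
})

test_that("semi-supervised matching unlocks downstream unsupervised rules", {
  # sample carries A0101 (library-covered) + B0101 (novel): the reference
  # motif anchors A0101, then rule 3 completes B0101
  lib <- reference_library(list(A0101 = jitter_pwm(motifs$X, seed = 21)),
                           c(A0101 = 21L))
  cat8 <- toy_catalog(
    list(s1 = list(motifs$X, motifs$Y)),
    genotypes = list(s1 = c("A0101", "B0101")))
  st0 <- annotate_unsupervised(cat8)
  expect_identical(nrow(st0$assignments), 0L)
  st <- annotate_semisupervised(cat8, st0, lib)
  got <- st$assignments[order(st$assignments$motif_index), ]
  expect_identical(got$allele, c("A0101", "B0101"))
  expect_identical(got$rule, c("semi", "3"))

  # eligibility boundary: exactly 20 ligands is not enough
  lib20 <- reference_library(list(A0101 = jitter_pwm(motifs$X, seed = 22)),
                             c(A0101 = 20L))
  st20 <- annotate_semisupervised(cat8, annotate_unsupervised(cat8), lib20)
  expect_identical(nrow(st20$assignments), 0L)

  # two motifs within T of the reference PWM -> "exactly one" guard
  cat9 <- toy_catalog(
    list(s1 = list(motifs$X, jitter_pwm(motifs$X, seed = 23))),
    genotypes = list(s1 = c("A0101", "B0101")))
  st9 <- annotate_semisupervised(cat9, annotate_unsupervised(cat9), lib)
  expect_identical(nrow(st9$assignments), 0L)
})

test_that("pooled per-allele peptides are exact set unions", {
  m1 <- list(index = 1L, pwm = motifs$X, peptides = sprintf("P%03d", 1:120), n = 120L)
  m2 <- list(index = 1L, pwm = jitter_pwm(motifs$X, seed = 24),
             peptides = sprintf("P%03d", 101:180), n = 80L)
  m3 <- list(index = 2L, pwm = motifs$Y, peptides = "QQQQQQQQQ", n = 1L)
  cat10 <- motif_catalog(list(s1 = list(m1, m3), s2 = list(m2)),
                         genotypes = list(s1 = c("A0101", "B0101"), s2 = "A0101"))
  st <- annotation_state(cat10)
  st <- HLAdecon:::.add_assignment(st, "s1", 1L, "A0101", "1")
  st <- HLAdecon:::.add_assignment(st, "s2", 1L, "A0101", "1")
  pools <- pool_allele_peptides(cat10, st)
  expect_identical(length(pools$A0101), 180L)    # 120 + 80 - 20 shared
  expect_null(pools$B0101)                        # unannotated motif: nowhere
  expect_identical(pool_allele_peptides(cat10, annotation_state(cat10)),
                   list())
})
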