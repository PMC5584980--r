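Package: HLAdecon
Title: Unsupervised HLA-I Motif Deconvolution, Allele Annotation and
    Ligand Prediction from Immunopeptidomics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering HLA class I binding motifs in pooled
    immunopeptidomics samples and mapping them to alleles without prior
    knowledge of binding specificity. Peptide lists from multiple samples
    are deconvoluted into position weight matrix (PWM) motifs with a
    mixture-model EM algorithm, motifs are annotated to HLA-I alleles
    purely from allele co-occurrence across sample genotypes, and the
    pooled per-allele peptides train a PWM-based ligand and neo-antigen
    predictor with BLOSUM62 pseudocounts, mass-spectrometry background
    renormalization and empirical P-values against proteome decoys. A
    synthetic-data generator and a validation harness reproduce the
    method's computational experiments at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
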