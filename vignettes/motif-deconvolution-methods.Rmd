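---
title: "Methods: motif deconvolution, allele annotation and ligand prediction"
author: "HLAdecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif deconvolution, allele annotation and ligand prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HLAdecon)
```

# The problem

Mass-spectrometry immunopeptidomics measures the pool of peptides presented
by all HLA class I molecules of a sample at once. Each sample carries up to
six alleles (two per locus A/B/C), and the measurement does not say which
allele displayed which peptide. HLAdecon implements a three-stage method
that (i) splits each sample's peptide list into binding motifs, (ii) maps
motifs to alleles using only the pattern of allele sharing across samples —
no binding-affinity predictor and no prior motif knowledge — and (iii)
trains a per-allele position-weight-matrix (PWM) ligand predictor from the
pooled per-allele peptides, suitable for ranking candidate neo-antigens
from tumor exome data.

# Mixture-of-PWMs deconvolution

For one sample and one peptide length $L$ (9 and 10 are modelled;
lengths are treated independently), peptides are modelled as draws from a
mixture of $K$ position-independent PWMs. The E-step computes
responsibilities $r_{ik} \propto w_k \prod_{j=1}^{L} M_k[j, x_{ij}]$; the
M-step re-estimates each PWM from responsibility-weighted residue counts
with a Dirichlet smoothing count $\gamma = 0.1$ per residue per position
(keeping emissions strictly positive) and sets $w_k$ to the mean
responsibility. The log-likelihood is monotone over iterations; a run
stops when its relative change falls below $10^{-6}$ (at most 500
iterations).

**Initialization and restarts.** Responsibilities are initialized from a
symmetric Dirichlet(1) per peptide under a caller-provided seed. Five
random restarts guard against local optima; each restart runs a 15-iteration
burn-in and only the best (by log-likelihood) continues to convergence.
On well-separated motifs the burn-in reliably identifies the basin, and
running every restart to convergence gave the same selected optimum at
several times the cost.

**Background ("trash") component.** The per-sample deconvolution includes,
by default, one additional flat component with fixed uniform emissions and
a free mixing weight (`deconv_config(background_component = )`). MS
contaminant peptides match no allele motif; without the flat component
they cannot form their own cluster — a full extra PWM costs
$19 L K$-scale parameters that the contaminant likelihood gain never
repays under BIC — so they would be absorbed into motif clusters and
dilute anchor probabilities. A contaminant that happens to carry one of a
motif's two anchor residues still has higher posterior under that motif
than under the flat component; this residual absorption is intrinsic to
maximum-posterior assignment and bounds how far contamination effects can
be suppressed (see *Limitations*).

**Model selection.** The number of motifs is chosen by BIC,
$-2\log\mathcal{L} + \nu \log n$ with $\nu = (K - 1) + 19 L K$ free
parameters (plus one with the background component). BIC is deliberately
conservative: two motifs that differ at a single anchor position carry a
per-peptide log-likelihood gain that exactly cancels against the mixing
entropy, so motif pairs are resolvable only when they differ at both
anchors — which is why the synthetic truth generator draws anchors without
replacement per position.

**Two-stage procedure.** `deconvolve_sample()` first fits a mixture with
$K$ fixed to the number of distinct HLA-A plus HLA-B alleles (these loci
are more highly expressed and dominate the signal), then re-fits with $K$
selected by BIC over $1..(\text{genotype size} + 1)$. The annotation
pipeline consumes the stage-2 motifs.

# Annotation by allele co-occurrence

Motif comparison uses the length-normalized squared Euclidean distance
$D^2 = \tfrac1L \sum_{j,A} (M[j,A] - M'[j,A])^2$ with threshold
$T = 0.078$; distances at exactly $T$ count as similar. Four rules are
applied in order, with an inconsistency-elimination sweep after each, and
the pass repeats until nothing changes:

1. **Shared allele.** For an allele carried by two or more samples and not
   yet annotated anywhere, search for a selection of exactly one
   unannotated motif per sharing sample with all pairwise distances within
   $T$. Only a *unique* such clique is accepted; two mutually consistent
   cliques (e.g. two alleles with identical sample incidence) defer the
   decision.
2. **All but one.** If one sample's genotype equals another's plus exactly
   one extra allele, and exactly one of its motifs has no counterpart
   within $T$ in the other sample, that motif belongs to the extra allele.
3. **Last remaining.** A sample with exactly one unannotated motif and one
   unannotated allele matches them.
4. **Propagation.** An allele with annotated motifs is searched for in
   every other sample that carries it: a unique unannotated motif within
   $T$ of *all* of the allele's motifs is annotated (requiring similarity
   to all, not to a consensus, is the stricter of the two readings).

Inconsistency elimination: while any same-allele motif pair exceeds $T$,
the motif with the largest mean distance to the allele's other motifs is
returned to the unannotated pool; exact ties are all removed, so a
mutually inconsistent pair loses both members. The loop terminates because
a pass that changes nothing ends it and passes are capped at the motif
count.

Alleles identifiable only by their co-occurrence structure can remain
unannotated in single samples (for example two near-identical HLA-C
motifs); other samples carrying only one of the pair resolve them. The
semi-supervised pass (`annotate_semisupervised()`) additionally matches
unannotated motifs against a reference compendium of per-allele PWMs,
accepting an allele only when it has more than 20 supporting ligands and
exactly one motif in the sample lies within $T$ of its reference PWM; the
unsupervised pass is then re-run so new anchors can unlock rule-3/4
completions for alleles absent from the compendium.

Statistical support for an annotation is an empirical P-value: the
distance between two same-allele motifs is ranked against the distances
from the first motif to every compendium motif (excluding the allele
itself), $P = (1 + \#\{d_r \le d_\text{obs}\})/(1 + N)$ — the add-one
rule keeps $P > 0$. A Bayesian likelihood-ratio column score (Dirichlet
priors, $\alpha_j = 1$, MS background) is available as an alternative
similarity; multinomial coefficients are omitted uniformly from all three
marginal terms, which leaves pair orderings (the only thing the empirical
P-value consumes) unchanged.

# The ligand predictor

Peptides annotated to an allele are pooled (set union) across samples.
The per-allele PWM adds BLOSUM62 substitution pseudocounts: per position,
$p = (\alpha f + \beta g)/(\alpha + \beta)$ with $f$ the observed
frequencies, $g_A = \sum_B f_B\,\rho_{BA}$, data weight $\alpha = n - 1$
and $\beta = 200$. The conditional matrix $\rho_{BA} = P(A \mid B)$ is
derived from the published integer BLOSUM62 half-bit log-odds matrix by
recovering the joint residue-pair frequency table it encodes: with
$o_{ij} = 2^{s_{ij}/2}$, marginal consistency of
$q_{ij} \propto p_i p_j o_{ij}$ forces $o\,p = \text{const}$, so the
marginals are the normalized solution of a single linear system and
$\rho = q / \text{rowSums}(q)$. This reconstruction avoids transcribing a
~210-entry table by hand and is exact up to the integer rounding already
present in the published matrix.

A peptide $x_1..x_N$ scores
$S = \tfrac1N \sum_i \ln\!\big(p_{x_i,i} / q_{x_i}\big)$ (natural log;
rankings are base-invariant). The renormalization background $q$ is the
mean, across alleles, of residue frequencies at the non-anchor positions
P4–P7 of each allele's pooled 9-mers, excluding alleles with known
specificity there; zero entries are floored at $10^{-4}$ (cysteine is
strongly under-detected in MS data, making zeros reachable) and the
vector renormalized. When nothing could be annotated, the pipeline falls
back to a proteome-like composition so scoring still works.

A peptide's final score is the maximum over the alleles considered, and
its empirical P-value ranks it against the max-over-alleles scores of
random proteome peptides (100,000 by default; the background is drawn once
per model set, length and seed). Neo-antigen mode enumerates every 9- and
10-mer window covering a missense mutation (alternate residue
substituted, duplicates merged), restricts to the patient's HLA-A/B
alleles (HLA-C is weakly expressed; a flag re-enables it), and ranks by
descending score with lexicographic tie-breaks. Benchmarks report the
rank-statistic AUC (ties count 1/2) and PP1%, the fraction of positives
among the top $\lceil 1\% \rceil$ of predictions — with 99-fold decoys
this equals both precision and recall.

# The synthetic-data generator

The generator defines the study conditions for every computational
experiment; it emulates the structure of real pooled immunopeptidomics
data, not any particular measurement.

* **Truth motifs.** Each allele's PWM has anchors at P2 and the C-terminus
  with probability 0.9 on one anchor residue, the remaining mass spread
  over the other residues in background proportion. Anchors are drawn
  without replacement per position (at most 19 alleles), so every allele
  pair differs at both anchors and all truth distances exceed $2T$;
  cysteine is excluded from anchor candidates because the MS detection
  bias would erode the anchor in the data. Non-anchor positions follow a
  human-like residue composition. "Confusable pairs" (truth distance
  below $T$) can be requested to emulate near-identical allele pairs.
* **Cohorts.** The standard design has 10 samples over 15 alleles (5 A,
  6 B, 4 C), genotype sizes 3–5, with an incidence matrix built so each
  rule has work: most alleles are shared by 2–4 samples (rule 1), sample
  S07 is S01 minus C01:01 (rule 2), and B06:01 occurs only in S05 where it
  is the last remaining motif (rule 3). No two alleles have identical
  sample incidence — co-occurrence methods cannot, in principle,
  distinguish such pairs. Samples draw 4,000 peptides per length
  (matching the depth of in-depth real datasets, ~47,000 peptides over 10
  samples) with uniform allele mixing; sampled peptides have cysteine
  probabilities multiplied by 0.2 (the bias lives in the data, the truth
  PWMs stay unbiased). Contaminants are injected as uniform-residue
  peptides at a configurable fraction, and ground-truth peptide labels are
  kept as a sidecar so tests can score annotations exactly.
* **Reference libraries, proteomes, mutations.** Library PWMs are built
  from sampled truth ligands with a flat +1 count, padded with
  random-anchor motifs to compendium size (107 for the P-value
  experiments); proteomes are i.i.d. draws from the human-like
  composition; mutation tables place random substitutions, optionally
  planting one neo-antigen whose mutated peptide carries a chosen
  allele's anchors while the wild-type sequence does not.

What passing these tests shows — and does not. The generator's motifs are
position-independent with exactly two single-residue anchors and flat
middle positions; real motifs have multi-residue anchor sets, residual
middle-position preferences, inter-position correlations, allele-specific
expression imbalance (HLA-C is often weak) and length coupling. Perfect
annotation on synthetic cohorts therefore demonstrates the co-occurrence
logic, not real-data deconvolution difficulty; conversely, the
matched-decoy ceiling below is *harsher* than reality in one respect
(two residues fully determine binding here).

# Numerical choices and problem sizes

Experiments in the test suite and the acceptance script use: 3-motif
mixtures with 9,000 peptides for recovery; 20 replicate 10-sample cohorts
for annotation soundness; 1,000 trials against 107-motif libraries for
P-value calibration (the library is regenerated per trial — against a
single fixed library the empirical P-values inherit the library's own
sampling fluctuations, ~$1/\sqrt{107}$, and a 1,000-trial KS test would
reject uniformity for that reason alone); 100 positives against 9,900
decoys per allele for discrimination; 10 replicate cohorts for
sub-sampling convergence; 50-mutation candidate lists for the hold-out
ranking. These sizes were chosen to estimate each quantity well at
desk scale.

# Known limitations

* **Benchmark ceiling from motif-matching decoys.** A random proteome
  9-mer carries both anchor residues of an allele with probability
  $f(a_2) f(a_\Omega)$ (~0.3% under human-like composition). Such decoys
  are statistically indistinguishable from true PWM-drawn ligands, so at
  99-fold decoy excess the per-allele PP1% is capped near
  $1/(1 + 99 f_2 f_\Omega)$ — about 0.75 on average across random anchor
  pairs — and the ~10% of sampled ligands that miss an anchor (anchor
  probability 0.9) cap the mean AUC near 0.98. These ceilings match the
  performance scale reported for real eluted-ligand benchmarks and should
  be read as properties of the benchmark, not of the implementation.
* **Contaminant absorption.** With the background component, contaminants
  carrying one anchor residue of a co-occurring motif still pool with it,
  shifting pooled anchor entries by a few hundredths at 5% contamination.
* **Annotation identifiability.** Alleles with identical sample incidence,
  or present in a single sample without a rule-2/3 pattern or reference
  motif, remain unannotated by construction.
* Lengths are modelled independently; 11–14-mers are ingested and carried
  through I/O but not deconvoluted or scored.
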