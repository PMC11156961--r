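---
title: "Methods: proteome-wide MR and omics integration for mitral valve prolapse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteome-wide MR and omics integration for mitral valve prolapse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valvemr)
```

# Overview

`valvemr` implements an integrative analysis that asks whether circulating
blood proteins causally influence the risk of mitral valve prolapse (MVP),
and what the candidate proteins do once identified. The pipeline has three
arms:

1. **Causal inference.** Two-sample Mendelian randomization (MR) of each
   blood protein on MVP risk, using cis protein quantitative trait loci
   (cis-pQTLs) as instruments, with weighted-median, MR-Egger, Cochran's Q
   and Steiger sensitivity analyses, and cohort-level multiplicity control.
2. **Tissue context.** Differential expression in mitral valve leaflets,
   immune-cell deconvolution and cytokine activity scoring of the same
   expression data, and gene-set enrichment of the results.
3. **Integration.** Candidate proteins are mapped onto a curated
   protein–protein interaction (PPI) network (degree, maximal cliques,
   voterank influence, walktrap modules), onto ligand–receptor pairs and
   cardiac cell-type gene sets, and onto drug–gene interactions under
   direction-aware actionability rules.

Every input class has a seeded generator with planted ground truth
(`sim_*` functions), so each stage is validated by parameter recovery
rather than by comparison with unavailable external services.

# Two-sample MR

## Instruments

For each protein, candidate instruments are variants on the protein's
chromosome within **250 kb of the transcription start site** (inclusive at
both ends), with association p-value **below 1e-5** and minor allele
frequency **at least 1%** (5% in the replication re-run). Greedy LD
clumping (`ld_clump()`) then mirrors PLINK's `--clump`: the best remaining
variant by p-value is kept and everything with r² ≥ 0.1 to it is discarded;
ties are broken by larger |z| and then lexicographic variant id, which makes
the output invariant to input row order. A protein is analyzable with at
least **three** independent instruments. Instrument strength is summarized
per variant as F = β²/SE²; weak instruments (F < 10) are flagged, not
removed, because instrument strength is reported as a property of the data
rather than used as a filter.

The MAF-vs-clumping order is unstated in the source analysis; this
implementation filters MAF first (the two operations commute because the
MAF filter is marginal per variant).

## Estimators

With harmonized per-variant effects (βx on the protein in SD units, βy on
MVP in log-odds), the per-variant Wald ratio is θⱼ = βyⱼ/βxⱼ with
first-order SE = SEyⱼ/|βxⱼ|. The **IVW** estimate is the weighted mean of
the θⱼ with weights wⱼ = βxⱼ²/SEyⱼ²; Cochran's **Q** = Σ wⱼ(θⱼ − θ̂)² on
n−1 df measures heterogeneity. The default model is multiplicative random
effects: the IVW SE is inflated by max(1, √(Q/df)), matching the default of
the commonly used MR software; a fixed-effect model is available by flag.
With one instrument the IVW reduces exactly to the Wald ratio and the
heterogeneity test is undefined (the interface contract nominally demands
n ≥ 2, but the single-instrument identity is the more useful behavior and
is what the estimator algebra gives; the package allows n ≥ 1).

The **weighted median** orders the Wald ratios, places each at the
cumulative weight midpoint sⱼ = Σᵢ≤ⱼ wᵢ′ − wⱼ′/2 (normalized weights), and
interpolates at s = 0.5; it is consistent while valid instruments carry
more than half the weight. Its SE comes from a seeded parametric bootstrap
(default 1000 draws; βx and βy perturbed by their SEs).

**MR-Egger** orients every instrument so βx ≥ 0 (flipping both betas — the
orientation on which "directional" pleiotropy is defined), then fits a
weighted least-squares regression of βy on βx with a free intercept and
weights 1/SEy². The intercept estimates average directional pleiotropy
(two-sided t test, n−2 df); the slope is a pleiotropy-robust causal
estimate under the InSIDE assumption. The plain WLS standard errors are
used (the random-effects flavor); on noiseless exact-fit inputs the
residual variance is zero and the intercept p-value is reported as
computed from a degenerate t statistic.

**Steiger filtering** guards against reverse causation: per variant, the
variance explained on each trait is approximated from the association
z-score as r² = z²/(z² + n − 2); the variant is kept iff it explains
strictly more exposure than outcome variance, and the direction p-value is
a one-sided z-test on the difference of Fisher-transformed |r|. Applying
the continuous-trait relation to the binary outcome's observed-scale
z-score is an approximation, stated as such; the case fraction is recorded
but not used.

## Multiplicity and the robustness filter

BH FDR and Bonferroni corrections are computed **per exposure cohort over
the proteins actually tested** (those with ≥ 3 instruments). A protein is a
candidate when FDR(IVW) < 0.05, Cochran's Q p > 0.05 and FDR(WM) < 0.05
simultaneously. The replication re-run repeats the whole per-protein
pipeline with MAF ≥ 5% instruments.

# The synthetic two-sample world

`sim_cis_region()` builds AR(1) LD (r_ij = ρ^|i−j|, positive definite by
construction) with uniform MAFs in 0.05–0.5. `sim_two_sample()` draws true
variant effects on the protein with |effect| uniform in **0.05–0.2 SD**
(cis-pQTL scale; the implied instrument F at the aptamer-cohort size is
~40–600, comfortably above the conventional threshold of 10), propagates
them through LD, and emits summary statistics with the analytic standard
errors SEx = 1/√(2·maf·(1−maf)·n_exp) and, for the binary outcome,
SEy = 1/√(2·maf·(1−maf)·n_out·cf·(1−cf)). The defaults are the real
cohort scales: n_exp = 35,559 (aptamer panel), n_out = 439,533 with
cf = 4884/439,533 (the MVP GWAS), 17 instruments per protein (the
aptamer-cohort median instrument count).

**Pleiotropy orientation.** Invalid instruments receive a direct outcome
effect equal to `offset` *on the exposure-increasing allele orientation*
(α = offset·sign(b)). With offsets attached to arbitrary reported alleles,
a nominally "directional" offset averages out across instruments of mixed
orientation: it is not directional in Wald-ratio space, IVW is nearly
unbiased, and the Egger intercept's estimand is no longer the planted
offset — the generator would not emulate the phenomenon it claims to.
Sign alignment is the standard construction in the MR simulation
literature and matches the orientation MR-Egger itself imposes.

**The robustness-contrast world.** The acceptance check that the weighted
median's bias stays below half of IVW's under 40% invalid instruments
only makes sense below the estimator's published breakdown bound, which is
stated in terms of *weight*, not count. With wide MAF and effect ranges,
40% of instruments by count carry more than 50% of the weight in roughly a
quarter of random draws, and there the weighted median fails by design —
no implementation could pass. That check therefore uses comparable weights
(MAF 0.2–0.4, |effect| 0.12–0.18), keeping the invalid weight share at
0.41 ± a few percent. Similarly, the bias ratio has the closed form
≈ 1.04·SEy/(f·offset), independent of instrument strength; at the MVP-GWAS
outcome noise (SEy ≈ 0.022) an offset of 0.1 makes the "less than half"
contrast unattainable (ratio ≈ 0.56) for any instrument strength, so the
contrast simulation plants offset 0.2, which shifts the invalid Wald
ratios by ~0.6–4 — the same geometry as the estimator's defining use case
(valid ratios at 0.2, invalid at 0.8). The Egger-recovery check keeps
offset 0.1 on 50 instruments, where the intercept estimand equals the
planted value.

# Enrichment

Over-representation is the exact upper-tail hypergeometric test
P(X ≥ k) with fold enrichment (k/n)/(K/N), always against an **explicit
background** (in the real analysis, the 4316 autosomal proteins shared by
the two pQTL panels). Gene symbols are upper-cased and whitespace-stripped
before matching; no alias resolution is attempted. The test is one-sided
(enrichment only) and uses P(X ≥ k), the standard convention. The p-value
is validated against direct binomial-coefficient summation and, at tiny N,
against exhaustive subset enumeration.

# Network analytics

The PPI subnetwork is extracted from the seed proteins as the **first-order
induced subgraph**: seeds present in the PPI plus their direct interactors,
with *every* PPI edge among included nodes retained (`--order 0` restricts
to seeds only). Degree and maximal cliques (Bron–Kerbosch with pivoting)
and walktrap community detection (Pons–Latapy, 4-step walks, merge
sequence cut at maximum modularity) are delegated to igraph — these are
standard algorithms with a canonical implementation — but are wrapped with
deterministic canonical orderings and validated against exhaustive
enumeration oracles on small graphs. **voterank** has no R implementation
and is authored here: abilities start at 1, a node's score is the sum of
its neighbors' abilities, the top scorer is elected (lexicographic ties),
its ability zeroed, and each neighbor loses 1/⟨k⟩ ability (floored at 0),
with ⟨k⟩ the mean degree of the input graph computed once; the election
stops when the best score is ≤ 0. Module annotation reports the minimum-p
gene set per module via the hypergeometric machinery above.

# Expression

## Normalization

Variance-stabilizing normalization is approximated by per-sample affine
calibration (median/MAD matched across samples) followed by the
generalized log glog2(x) = log2((x + √(x² + c²))/2). Under the
additive + multiplicative error model x = μ·e^η + ε, the glog variance is
*exactly* constant when c = sd(ε)/sd(η); the offset is therefore fitted by
robust moments — additive SD from the spread of bottom-decile features,
multiplicative SD from the CV of top-decile features. An earlier rule
(c = 5th intensity percentile) was abandoned because the 5th percentile of
intensity is unrelated to the noise ratio: on the stated noise model it
left a 14-fold SD gradient across intensity deciles, against the
contract's 2-fold bound. The percentile rule survives only as a fallback
for degenerate inputs (single sample or noise-free data). Acceptance is
the variance-flatness property, not numeric equality with any particular
vsn implementation.

## Differential expression

Probes mapping to one gene are collapsed by per-sample median. The
moderated t statistic follows the standard empirical-Bayes treatment:
per-gene pooled variances s²_g on d_g df are shrunk through the scaled-F
method-of-moments fit (limma's `squeezeVar` provides the canonical
hyperparameter fit), the posterior variance is
(d₀s₀² + d_g s²_g)/(d₀ + d_g), and p-values use d₀ + d_g df with BH FDR
across genes. Setting d₀ = 0 recovers the ordinary t-test exactly and
d₀ = ∞ pools all genes, both exposed for testing. The full path is
cross-checked against `limma::eBayes` (agreement to ~1e-8 on t; limma
additionally caps the total df at the experiment-wide residual df, which
can move p-values in the 4th decimal). DE genes are reported at
**|log2FC| > 1.25 and FDR < 5%**, both strict, reading the fold-change
threshold on the log2 scale as in the source figure's axis. The group
difference is case − control (second factor level minus first)
everywhere.

## GSEA

Genes are ranked by fold change; the enrichment score is the weighted
Kolmogorov–Smirnov running sum (hit increments ∝ |score|^p, p = 1 by
default; uniform miss decrements). Significance uses **gene-label
permutation** (the set's positions are redrawn uniformly), the natural
null for a fold-change-ranked list; with only 24 arrays, phenotype
permutation would be viable but operates on a different input than the
ranking this stage consumes. NES divides ES by the mean |ES| of same-sign
permutations, and the FDR is the standard pooled positive/negative
procedure. A set covering the whole universe leaves the miss decrement
undefined and is an error.

# Deconvolution

Cell-type proportions are estimated in the GEDIT mould: per-type signature
genes scored by max/second-highest specificity, rows scaled to [0, 1] and
raised to power 0.9 to damp dominant genes, and a per-sample
**non-negative least squares** fit (Lawson–Hanson active set, authored
here because no NNLS solver ships with the installed stack) renormalized
to proportions.

Two deliberate deviations from the original recipe, both forced by the
module's own contracts:

* **No mandatory quantile normalization.** Mapping bulk columns onto the
  pooled genes × types reference distribution (dominated by every type's
  marker highs) distorted same-platform mixtures so badly that per-type
  recovery RMSE was ~0.18 against the 0.05 bound; normalizing both
  matrices to a shared target restored exact purity but broke noiseless
  50/50 mixtures (0.40/0.60). Quantile normalization is genuinely a
  cross-platform harmonization step, so it is exposed as an option
  (`quantile_target`) and off by default.
* **Row scaling by the reference maximum with no per-gene shift.** The
  transform (x/max_ref)^0.9 is positively homogeneous, which makes
  proportions exactly invariant to global rescaling of a bulk sample
  (NNLS is a cone problem; renormalization cancels the factor), recovers
  a pure reference column exactly, and keeps noiseless mixtures within
  2e-4 at power 0.9 (exact at power 1). A min–max scaling with per-gene
  shifts breaks all three properties.

With these choices, 22-type mixtures at multiplicative noise SD = 0.1 of
signal are recovered with per-type RMSE < 0.02 and per-type
truth–estimate correlation > 0.99 (bounds 0.05 and 0.95). Group
comparison of proportions is an unpaired two-sided t-test per cell type
with BH across types; constant-in-both-groups types are reported at p = 1
with a warning. PCA of the proportion matrix is SVD on centered,
unit-variance-scaled columns.

# Cytokine activity

Per-sample differential profiles (grand-mean centering by default, since
both groups are scored; control-mean centering differs only by a per-gene
constant) are regressed on the cytokine response signature matrix by ridge
regression, β = (SᵀS + λI)⁻¹Sᵀy with λ = 1e4 (the published default of the
cytokine-activity framework). The activity z-score standardizes each
coefficient against a permutation null (1000 seeded gene-label
permutations of y). The z-scores are invariant to a global rescaling of
the signature provided λ scales with the square of the factor (same
regularization geometry); the solver is validated against the normal
equations to 1e-8. Differential activity between groups is a Wilcoxon
rank-sum test (exact when both groups have ≤ 12 samples and no ties;
normal approximation with tie/continuity correction otherwise). The
cytokine dendrogram clusters the Pearson correlation profiles of cytokine
activity vectors by Euclidean distance; linkage defaults to complete (the
source is silent) and the tree serializes to Newick.

# Integration and actionability

Candidate proteins (direction +1 when OR > 1) are joined to
ligand–receptor pairs (candidate as ligand or receptor; curated additions
carry their own source label), receptors are tested for cardiac cell-type
enrichment against the explicit background, and interactions are annotated
with the tissue partner's DE statistics. Drug–gene rows are partitioned
exhaustively into actionable / non-actionable / unclassified:

* risk-increasing candidate + inhibitor-class drug (inhibitor, antagonist,
  blocker, neutralizer, ...) on the candidate or its receptor → actionable;
* risk-decreasing candidate + agonist-class drug → actionable;
* risk-decreasing **soluble (decoy) receptor**: drugs that neutralize its
  cognate ligand are actionable, because the decoy itself lowers ligand
  signaling — codified from the worked decoy example in the source
  analysis (a soluble interleukin-1-receptor-family protein sequestering
  its alarmin ligand);
* unrecognized action verbs are kept, flagged "unclassified action".

The first two rules are direction-antisymmetric by construction (flip the
direction and swap inhibitor ↔ agonist); the decoy rule is interpretive
and deliberately asymmetric. Action verbs are normalized through a bundled
synonym table.

# Pipeline

`run_pipeline()` executes the enabled stages in dependency order from a
YAML or programmatic configuration whose thresholds default to the
analysis' published settings. Every run writes a manifest (seed, resolved
thresholds, input checksums, per-stage input/output checksums keyed by
*relative* paths); a stage re-runs only when its inputs changed or an
output fails its checksum (corrupted cache). No output contains a
timestamp, so identical configurations produce byte-identical run
directories — verified in the acceptance suite. `pipeline_report()`
collates stage outputs without recomputation.

# What a green test establishes — and what it does not

The generators emulate the *structure* of the real inputs (summary
statistics with analytic SEs and planted causal effects, marker-structured
references, signature-driven responses, planted communities and overlaps),
not their full complexity: no realistic human LD panel, no winner's-curse
selection of instruments, no cross-platform batch structure, no
probe-level microarray artifacts, and gene-symbol universes that are
disjoint from real annotation. Recovery at the stated noise levels
demonstrates that the estimators and their plumbing are correct, not that
the biological conclusions of any particular dataset are reproduced.
Paper-scale headline numbers (counts of candidate proteins, the 440-node
network, specific enrichment folds) require the original multi-gigabyte
downloads and are out of desk-scale scope by design.

# Numerical choices and degenerate inputs

* Palindromic (A/T, C/G) variants with exposure EAF in (0.42, 0.58) are
  dropped during harmonization by default (conservative community default;
  the source is silent); others are aligned by allele identity.
* Indels and multi-allelic records are dropped with reason codes; all QC
  drops are counted per reason in machine-readable reports.
* Variant-id overlap below 10% of the smaller table triggers a
  genome-build-mismatch warning (build conversion is out of scope).
* p-values inconsistent with |β/SE| by more than a factor of 10 warn but
  do not drop (validation, not censorship).
* Hypergeometric p at k = 0 is exactly 1; empty queries give fold 0.
* Zero-variance cytokines are excluded from dendrograms, zero-variance
  features from PCA, both with warnings.
* All stochastic operations take explicit seeds; derived child seeds stay
  below 2³¹.

# Known limitations

* The weighted-median bootstrap perturbs βx and βy independently
  (no exposure–outcome correlation; two-sample designs justify this).
* Steiger r² for the binary outcome is an observed-scale approximation;
  liability-scale conversion is not implemented.
* The Egger intercept SE uses plain WLS; the "no underdispersion" variant
  (dividing by min(1, σ̂)) is not implemented.
* GEDIT's exact numeric output is not reproduced (by design; acceptance is
  recovery-based).
* The PPI loader applies no species/evidence filters (exposed upstream of
  this package's scope).
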