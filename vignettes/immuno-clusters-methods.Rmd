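---
title: "Immuno-cluster discovery and systemic inflammation: models and methods"
author: "immunoCohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immuno-cluster discovery and systemic inflammation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunoCohort)
```

## The scientific setting

Triple-negative breast cancer (TNBC) lacks the three receptors targeted by
endocrine and anti-HER2 therapy, so characterizing its immune landscape is
the main route to stratifying patients for immunotherapy. Two views of that
landscape are combined here. The *local* view comes from bulk tumor
expression: signature scores for cytolytic activity and T-cell inflammation,
stromal/immune content, immune-cell composition, and an unsupervised
decomposition of the cohort into immuno-clusters — an inflamed ("hot")
group, an immune-excluded ("cold") group and an intermediate one. The
*systemic* view comes from a routine complete blood count: the
platelet-to-lymphocyte ratio (PLR) and neutrophil-to-lymphocyte ratio
(NLR). The package's purpose is to make the whole chain — clustering,
scoring, deconvolution and the association statistics linking the two
views — reproducible on any genes-by-samples log2 expression matrix, with a
synthetic cohort generator supplying ground truth for every stage.

## Per-sample signature scores

All scores operate on log2-scale expression; an `ImmunoExperiment` carries
a `scaleTag` and every consumer converts explicitly (`exprsOn(x, "log2")`),
never by guessing from value ranges.

* **CYT** (cytolytic activity): the geometric mean of GZMA and PRF1
  expression, computed as the arithmetic mean of the two log2 values and
  reported in log2 units. Adding a constant to every log2 value shifts CYT
  by exactly that constant (location equivariance).
* **TIS** (tumor inflammation signature): the unweighted mean of log2
  expression over an 18-gene T-cell-inflamed panel. The panel is an
  editable text file (`inst/extdata/tis_genes.txt`); absent genes are
  dropped with a warning. A housekeeping-normalized variant can be obtained
  by normalizing the matrix before scoring; the score itself stays a plain
  mean because the source definition is ambiguous on this point.
* **Aggressive score**: the fixed linear combination
  $-0.393\,\mathrm{CCL5} + 0.443\,\mathrm{DDIT4} + 0.490\,\mathrm{POLR1C}$
  of log2 expression. The coefficients are published constants and are not
  tunable in practice.
* **IMS** (integrative immune score):
  $\mathrm{IMS} = \mathrm{CYT}\times\mathrm{TIS} - \mathrm{Aggressive}$,
  enforced exactly (to machine precision) by the `SignaturePanel` validity
  method.
* **ssGSEA**: per sample, genes are ranked by expression (average ranks for
  ties; the descending walk breaks expression ties by gene name so input
  order never matters). The running sum accumulates an in-set CDF weighted
  by $\mathrm{rank}^\alpha$ (normalized by the in-set total) against a
  uniform out-of-set CDF; the enrichment score is the summed deviation.
  Defaults: $\alpha = 0.25$ and cohort-range rescaling on, both exposed
  because only the minimum set size (5) is fixed by the source; sets below
  the minimum are skipped with a warning, not an error.
* **ESTIMATE-style scores**: stromal and immune scores are unnormalized
  ssGSEA enrichment of two marker panels (compact editable defaults, not
  the original published panels); the combined score is their sum, and
  purity is $\cos(0.6049872018 + 0.0001467884\,\mathrm{score})$. Purity is
  reported only while the cosine argument stays within $[0, \pi/2]$;
  outside that domain it is NA rather than a clamped, fabricated fraction.
  At a combined score of zero the closed form evaluates to 0.82252.
* **Immunophenoscore**: genes are z-scored across samples; each of four
  categories (MHC, immunomodulators, effector, suppressor — a compact
  editable weight table) contributes a weighted mean of gene z-scores; the
  raw score is the category mean, discretized as 0 when raw ≤ 0 and
  otherwise $\lceil 10\,\mathrm{raw}/3 \rceil$ capped at 10. The
  discretization rule is stated explicitly because only endpoint values are
  reported by the sources this emulates.

Median dichotomization sends ties to the low ("≤ median") group everywhere,
and the TILs-high flag is inclusive at its 20% threshold — one convention,
applied uniformly.

## Consensus NMF clustering and refinement

The clustering substrate is the immune-gene submatrix, shifted nonnegative
by subtracting its global minimum (recorded), and optionally filtered to
the most variable genes. Factorization uses the classical multiplicative
updates for the squared-Euclidean objective, which keep the objective
non-increasing; runs stop at a relative objective change below `tol` or at
`maxIter`. Each of `nRuns` random restarts assigns every sample to the
argmax row of H (ties to the lowest index); the consensus matrix holds
co-assignment frequencies, and stability is the Pearson correlation between
the consensus distances and the cophenetic distances of their
average-linkage dendrogram.

Rank selection maximizes the cophenetic coefficient over a grid with ties
going to the smallest rank. A tie is defined numerically: the consensus
matrix is a Monte-Carlo estimate from `nRuns` restarts, so its cophenetic
coefficient carries sampling error of order $1/\sqrt{\mathrm{nRuns}}$;
differences within `tieTol` (default 0.003) are therefore not ranked by
their meaningless trailing digits. Without this, the chosen rank flips
between adjacent values on differences of ~0.001.

Refinement mirrors the two-step procedure that turned five mathematical
clusters into three biological ones: (1) clusters smaller than
`minSize` (default `max(4, 10% of n)`) are excluded outright and their
samples dropped from all downstream statistics; (2) while more than
`targetK` clusters remain, the pair with the most Pearson-correlated
mean-expression centroids is merged (size-weighted centroid update). Both
steps are deterministic given labels and centroids and every action is
logged. Final clusters are renamed ImA/ImB/ImC by descending mean immune
score, so ImA is always the inflamed cluster. The pipeline refines from the
most stable rank at or above `targetK`, since merging can only reduce the
cluster count.

## Deconvolution

Immune-cell composition is estimated per sample by linear nu-support-vector
regression of the z-scored linear-scale mixture on the z-scored columns of
a user-supplied signature matrix, over a nu grid (0.25/0.5/0.75) with the
lowest-RMSE fit retained; negative coefficients are zeroed and the
survivors normalized to fractions summing to one. Significance comes from a
permutation null that resamples the mixture values (p-values are plus-one
corrected, so they live in (0, 1]). The published 22-type signature matrix
is not bundled; any genes-by-types TSV works, and the tests use a 5-type
synthetic matrix with block markers. Fractions are invariant to positive
rescaling of the mixture because of the z-scoring.

## Association statistics

PLR and NLR are plain count ratios (platelets/lymphocytes,
neutrophils/lymphocytes), undefined for nonpositive lymphocytes. The 2x2
odds ratio is $(ad)/(bc)$ with the Wald interval
$\exp(\log\mathrm{OR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$ — Wald rather than
profile-likelihood throughout, because Wald intervals reproduce the
reference association tables exactly from their reconstructed cells. Zero
cells flag the OR undefined; a Haldane–Anscombe +0.5 correction is
available but off by default. Binomial logistic regression is the `glm`
IRLS fit; multinomial regression (baseline-category logit, `nnet`) reports
ORs per 10 units for PLR and per unit otherwise, with optional age
adjustment as a binary ≥50 indicator (continuous age behind a flag, since
the emulated cohort reports age only in those strata). Spearman,
Kruskal–Wallis (tie-corrected) and Fisher's exact tests come from base R;
five-year disease-free survival uses the product-limit estimator and the
log-rank test from the survival package. No multiple-testing correction is
applied by default, matching the reporting style this package emulates.
Quadrant classification of marker-vs-time scatters assigns boundary values
to the low side (Q2 high/high, Q4 high/low, Q1 low/high, Q3 low/low).

## The synthetic cohort generator

`syntheticConfig()` encodes the study conditions: 54 samples in clusters of
15/18/21 (ImA/ImB/ImC); 708 immune-program genes plus 2000 background
genes; shared immune activation shifts of +1.5/0/+0.5 log2 units; Gaussian
log2 noise with sd 0.6; TILs linked linearly to the per-sample CD8-program
mean (intercept −70, slope 12 per log2 unit, noise sd 10, clamped to
[0, 100]); per-cluster lognormal PLR medians 132/162/176 carried by the
platelet draws over shared lognormal lymphocytes; exponential recurrence
with a 10% five-year event probability in ImA and a hazard ratio of 3 in
the non-inflamed clusters, administratively censored at five years.

One structural choice deserves emphasis: a single graded shift applied to
every immune gene makes cluster identity a one-dimensional scalar, and no
factorization-based clustering can recover three groups from a dominant
one-dimensional gradient — empirically, per-run NMF assignments carry zero
information in that regime. Real cohorts separate because each subtype also
expresses its own gene program (visible as distinct blocks in a clustered
heatmap and as three groups in a PCA). The generator therefore gives each
cluster a disjoint 100-gene identity module (carved from the unnamed
immune filler genes, +2 log2 in its own cluster), calibrated once so that
recovery experiments are meaningful and then frozen. All named signature
genes (GZMA, PRF1, CCL5, DDIT4, POLR1C, the TIS panel, the CD8 program,
the marker panels) are real HGNC symbols so every scoring operation runs
unmodified; DDIT4, POLR1C, the stromal markers and the regulatory genes are
background (cluster-independent), which yields the expected directions:
aggressive score lowest and CYT/TIS/IPS highest in ImA.

What the generator does *not* emulate: probe-level microarray noise, batch
effects, gene–gene correlation beyond the module structure, copy-number
structure, or the exact effect sizes of any real cohort. Passing recovery
tests therefore demonstrates that the pipeline's machinery is correct and
calibrated, not that it would achieve the same accuracy on clinical data.

## Numerical choices and problem sizes

* NMF: uniform random initialization from a per-run seed derived
  deterministically from one master seed; W columns rescaled to unit L2
  with compensation in H after convergence; `eps`-guarded denominators.
* Consensus runs in the recovery experiments use the 250 most variable
  immune genes, 30 restarts per rank, a 2–5 rank grid, `maxIter` 800 and
  `tol` 1e-6; the acceptance checks run 50 (tests) or 15 (script) cohorts
  at these sizes. These are the package's working sizes for a 54-sample
  cohort; larger cohorts warrant more restarts.
* Calibration checks use 5000 null simulations for the Kruskal–Wallis and
  logistic type-I error (the logistic null at n = 200, where the Wald test
  is in its asymptotic regime) and n = 3000 for the multinomial null.
* Degenerate inputs: constant score vectors dichotomize to all-low with a
  warning; all-censored survival groups yield flat curves with the log-rank
  still defined; empty reference classes, zero cells, separation and
  non-convergence are errors naming the offender.

## Known limitations

* The ssGSEA, ESTIMATE-style and immunophenoscore implementations follow
  the published definitions but are not byte-for-byte ports of the
  original third-party code; gene panels and weights are editable defaults,
  so absolute score values depend on the configured panels even though
  orderings and invariants do not.
* Cohort-level reference values from the emulated study (median CYT 7.11,
  TIS 8.26, Spearman ρ = 0.728, purity 61%, and so on) require that study's
  expression data and preprocessing; the package checks directions and
  orderings on synthetic cohorts and treats those numbers as documentation
  for an optional real-data mode.
* Rank selection inherits the known flatness of the cophenetic criterion
  near the true rank; the tie tolerance makes the smallest-rank preference
  explicit rather than pretending four digits of precision.
* The refinement's minimum-size and merge rules assume the initial
  clustering is at least as fine as the target; the pipeline enforces this
  by refining from a rank at or above the target.
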