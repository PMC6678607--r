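# immunoCohort

Tools for decomposing bulk tumor expression cohorts into immuno-clusters
and relating the local immune state to systemic blood-count inflammation
markers. The motivating setting is triple-negative breast cancer (TNBC),
where cohorts split into an immune-inflamed ("hot") cluster, an
immune-excluded ("cold") cluster and an intermediate one, and where the
platelet-to-lymphocyte ratio (PLR) from a routine blood test tracks the
local immune landscape. The package is aimed at computational biologists
who have a genes x samples log2 expression matrix plus per-patient blood
counts and clinical annotations, and want the whole analysis chain to be
reproducible and testable.

## What it computes

**Immuno-clusters.** Consensus nonnegative matrix factorization
(multiplicative updates, squared-Euclidean objective) on the immune-gene
submatrix; the factorization rank is selected by the cophenetic correlation
coefficient of the consensus matrix; a two-step refinement excludes
under-sized clusters and merges the most Pearson-correlated cluster
centroids down to the target count (default 3). Final clusters are renamed
ImA/ImB/ImC by descending immune score, so ImA is the inflamed cluster.

**Per-sample immune scores.**

- cytolytic activity `CYT = mean(log2 GZMA, log2 PRF1)` (the log2 geometric
  mean),
- tumor inflammation signature `TIS` = mean log2 expression of an 18-gene
  T-cell-inflamed panel,
- aggressive score `= -0.393 CCL5 + 0.443 DDIT4 + 0.490 POLR1C`,
- the integrative immune score `IMS = CYT x TIS - Aggressive`,
- ssGSEA rank-based enrichment for arbitrary GMT gene sets,
- ESTIMATE-style stromal/immune scores with tumor purity
  `cos(0.6049872018 + 0.0001467884 x score)`,
- a 0-10 immunophenoscore over MHC / immunomodulator / effector /
  suppressor gene programs.

**Deconvolution.** Immune-cell fractions per sample by linear
nu-support-vector regression against a user-supplied signature matrix,
with permutation p-values.

**Association statistics.** PLR/NLR from blood counts; crude and
age-adjusted odds ratios with 95% Wald intervals (2x2 and logistic);
multinomial logistic regression against the ImA referent (PLR per 10
units); Spearman, Kruskal-Wallis and Fisher tests; five-year Kaplan-Meier
disease-free survival with log-rank; quadrant classification of
marker-vs-time scatters.

**Synthetic cohorts.** `simulateCohort()` draws cohorts with known ground
truth (54 samples, clusters of 15/18/21, graded immune activation,
per-cluster identity gene modules, TILs linked to CD8 enrichment, PLR
lognormal medians 132/162/176, cluster-dependent recurrence hazards), so
every downstream stage can be validated against truth.

## Worked example

```r
library(immunoCohort)
bundle <- runPipeline(list(simulate = syntheticConfig(seed = 7), seed = 7))
cat(reportSummary(bundle), sep = "\n")
```

```
## Clusters

cluster | n | median_cyt | median_tis | median_aggressive | median_ims | median_plr | pct_tils_high
--- | --- | --- | --- | --- | --- | --- | ---
ImA | 15 | 8.804 | 8.763 | 3.066 | 74.71 | 117.0 | 80.00
ImB | 21 | 7.710 | 7.739 | 3.503 | 55.46 | 178.0 | 52.38
ImC | 18 | 7.182 | 7.239 | 3.709 | 48.55 | 175.5 | 44.44

## Associations

marker | contrast | estimate | ci_low | ci_high | p_value | scaling | adjustment
--- | --- | --- | --- | --- | --- | --- | ---
plr | kruskal-wallis | 20.7100 | NA | NA | 3.18e-05 |  |
plr | ImB vs ImA |  1.8800 | 1.2967943 | 2.725987 | 8.64e-04 | per-10-units | age-adjusted
plr | ImC vs ImA |  1.7870 | 1.2356311 | 2.584333 | 2.04e-03 | per-10-units | age-adjusted
tis_vs_plr | spearman | -0.4314 | NA | NA | 1.12e-03 |  |
tils_vs_cd8 | spearman |  0.4077 | NA | NA | 2.21e-03 |  |
plr_high_vs_aggressive_high | 2x2 |  2.8900 | 0.9575253 | 8.722589 | 5.97e-02 | per-unit | crude
```

Reading this: the pipeline recovered three clusters from the simulated
cohort; the inflamed cluster ImA has the highest median cytolytic activity
(8.80 log2 units), TIS and IMS, the lowest aggressive score, the lowest
median PLR (117 vs ~175-178) and the largest share of TILs-high tumors
(80%). The association table shows PLR differing across clusters
(Kruskal-Wallis p = 3e-05), PLR odds ratios per 10 units above 1 for the
non-inflamed clusters versus ImA, a negative TIS-PLR Spearman correlation,
and a positive TILs-CD8 correlation — the qualitative structure the method
is designed to surface. On real cohorts, replace the `simulate` block with
an `input` block pointing at an expression TSV/GCT, a CBC CSV and a
clinical CSV (see `?runPipeline`).

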