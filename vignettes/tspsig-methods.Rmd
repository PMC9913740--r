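---
title: "Discovering subtype-specific prognosis signatures in TNBC: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering subtype-specific prognosis signatures in TNBC: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Triple-negative breast cancer (TNBC) is not one disease. The TNBCtype-4
taxonomy distinguishes basal-like 1 (BL1), basal-like 2 (BL2), luminal
androgen receptor (LAR) and mesenchymal (M) tumors, which differ in biology,
prognosis and drug response. A prognosis signature fitted on all TNBC
patients jointly therefore blurs subtype-specific risk structure. The
`tspsig` package implements a pipeline that discovers a separate prognosis
signature per subtype (a *TSPSig*) from single-cell RNA-seq of cancer
epithelial cells, and then validates each signature on bulk cohorts with
survival outcomes and on drug-response panels.

The pipeline has six analysis stages, each a package module:

1. **Preprocessing** — QC filtering of a cells × genes UMI count matrix and
   pooling-deconvolution size-factor normalization.
2. **Subtype assignment** — correlation of each cell's expression profile
   with subtype centroids.
3. **Signature discovery** — the CM1 class-separation score per gene per
   subtype, top/bottom-k selection, cross-subtype overlap removal.
4. **Representativeness** — signature genes versus background genes on
   expression level, histogram entropy and inter-gene correlation.
5. **Survival validation** — risk scoring, maximally selected rank-statistic
   cutpoints, Kaplan-Meier/log-rank, proportional-hazards models, nomogram,
   calibration, time-dependent AUC.
6. **Drug sensitivity** — median-split rank-sum tests and Spearman
   correlations against ln(IC50) on subtype-labelled cell lines.

A synthetic-data module generates inputs with the statistical structure each
stage assumes, so the whole pipeline is testable end to end without any
external download.

# Preprocessing

`filter_genes()` retains protein-coding genes (configurable biotype set)
that are not mitochondrial or ribosomal and are detected in at least
`min_cells` cells; `filter_cells()` retains cells with at least `min_genes`
detected genes and, optionally, a required annotation label (the cancer
epithelial cells in the intended application; annotation itself is an input,
not something this package computes). The defaults `min_cells = 3` and
`min_genes = 200` are the conventional scRNA-seq QC choices; mitochondrial
and ribosomal genes are recognized by the symbol prefixes `MT-`, `RPL`,
`RPS`, all configurable, since no fixed gene list is universally right
across annotation releases.

`compute_size_factors()` implements pooling deconvolution. Cells are placed
on a ring ordered by library size (ties broken by cell id so the estimate is
invariant to input order). For each pool size in
`pool_sizes = c(21, 41, 61, 81, 101)` every window of consecutive cells is
summed into a pseudo-cell; the median over genes of the ratio between the
pooled profile and the average profile of all cells estimates the *sum* of
the member cells' factors. The resulting overdetermined linear system
(number of pools × number of cells) is solved by least squares with a tiny
ridge (1e-8) for numerical safety, and factors are rescaled to mean 1.
Pooling is what makes the estimate robust to the zero inflation that breaks
per-cell median-of-ratios estimators on UMI data. No clustering pre-step is
applied: the intended input is a single annotated cell population, so a
single deconvolution block suffices. If the solved system yields any
non-positive factor — possible on adversarial inputs with near-disjoint
gene support — the function falls back to library-size factors for *all*
cells and flags the result, rather than silently clipping.

Normalized expression is `log2(count / factor + 1)`. The log2(x+1)
transform on size-factor-scaled counts is the field's standard choice, and
every downstream module consumes this scale.

# Subtype assignment

`classify_subtypes()` correlates each unit (cell, bulk sample or cell line)
with each centroid column over the shared genes (Pearson on the log scale by
default, Spearman selectable) and assigns the subtype with the highest
*positive* correlation. Units with no positive correlation, or with a
zero-variance expression vector over the shared genes, are `"unassigned"`.
Exact correlation ties are broken by centroid column order with a warning —
deterministic behavior in preference to silent arbitrariness. The same
operation classifies cells, bulk samples and cell lines; only the centroid
matrix changes. Centroids are a user-supplied artifact: this package does
not re-derive any published subtype predictor, and the synthetic module
fabricates internally consistent centroids (the true per-subtype mean log2
expression).

`min_shared_genes = 20` guards against classifying on a handful of genes.
No significance filter is applied to the winning correlation; only its sign
is checked.

# The CM1 score and signature construction

For gene $i$ and a given subtype, with $x$ the expression values in the
subtype's cells and $y$ the values in all other assigned cells,

$$\mathrm{CM1}_i = \frac{\bar{x}_i - \bar{y}_i}{1 + (\max\{y_i\} - \min\{y_i\})}.$$

The numerator is the usual mean difference; the denominator penalizes genes
that are heterogeneous *outside* the subtype, which a t-statistic would not.
Two readings of the denominator are defensible: the range over individual
out-of-subtype cells, or over the per-subtype mean expressions. We take the
per-cell reading as the default (`range_over = "cells"`) and expose
`"subtype_means"` as a switch; on heterogeneous data the two differ, and
outputs record which was used. Cells labelled `unassigned` enter neither
group. CM1 is invariant to adding a constant to all values and flips sign
when group roles are mirrored with equal ranges — both properties are
tested.

`select_candidates()` ranks genes by CM1 descending and takes the first
$k = 4$ as up-regulated and last $k$ as down-regulated candidates, breaking
rank ties lexicographically by gene id. A sign guard drops any "up"
candidate with CM1 ≤ 0 and any "down" candidate with CM1 ≥ 0: up- and
down-regulation are defined by positive and negative class separation, and
a gene violating that is not a marker no matter its rank. `remove_overlaps()`
then removes any gene selected for two or more subtypes from *all* lists —
a gene shared between subtypes is, by construction, not subtype-specific.
The result is the pairwise-disjoint signature set.

# Representativeness

Three per-gene metrics contrast signature genes with the background (all
retained genes minus all signature genes): mean log-expression; Shannon
entropy in bits of a 10-bin equal-width histogram of the gene's expression
across cells (plug-in estimator; a constant gene has entropy 0, and
entropy is bounded by log2 of the bin count); and mean absolute pairwise
correlation within the gene set (Spearman by default). Because all-pairs
background correlation is both unpayable and structurally incomparable with
a 20-odd-gene signature, the background correlation metric is computed on
random background gene sets of the signature's size (seeded). Differences
are tested with a two-sided Wilcoxon rank-sum test — exact enumeration for
two tie-free groups of ≤ 20, tie-corrected normal approximation otherwise.
Signatures are pooled across subtypes for this comparison by default; the
functions accept any gene list, so per-subtype comparisons are a one-liner.

# Survival validation

**Risk score.** How a multi-gene signature becomes one number per patient is
the pipeline's largest free choice, and published practice varies. The
default is the signed z-mean: each signature gene is z-scored across the
cohort and averaged with down-regulated genes entering negatively. An
unsigned mean and the first principal component (sign-aligned with the
signed mean) are selectable, and every output records the mode used.

**Cutpoint.** `optimal_cutpoint()` implements maximally selected rank
statistics: every admissible threshold (both groups ≥ `minprop = 0.1` of
the cohort) is scored by the standardized two-group log-rank statistic and
the |z|-maximizing threshold is returned. The reported `p_naive` is the
log-rank p of the *selected* dichotomy. Because the split was optimized on
the same data this p is anti-conservative — under the null it rejects at
far above the nominal rate, which the test suite demonstrates rather than
hides (about 40–50% at α = 0.05 in the packaged null simulation). It is
reported because it is what Kaplan-Meier panels conventionally display; it
must not be read as a calibrated test.

**Models.** Kaplan-Meier curves, the two-group log-rank test and Cox
proportional-hazards fits stand on the `survival` package (Efron tie
handling; Wald 95% CIs; Breslow baseline cumulative hazard at the covariate
means). Stage is binarized as III vs I/II; chemotherapy and hormone therapy
are yes/no indicators. Endpoints (OS/RFS/DFI/MFS) share one engine via
column mapping. Univariate and multivariate analyses are laid out side by
side by `hazard_table()`. Monotone likelihood (e.g. complete separation) is
reported as an error naming the covariates rather than returning a
divergent fit. No multiplicity adjustment is applied; raw p-values are
reported.

**Nomogram.** `build_nomogram()` renders the multivariate model as a points
table: points(x) = 100·|β·(x − ref)| / max over covariates of |β·range|,
with ref the lowest-risk end of each covariate's range, so the covariate
with the largest |β|·range spans exactly 0–100. Total points map linearly
back to the linear predictor and hence to S0(t)^exp(lp) at each horizon.
Predicted survival is monotone nonincreasing in total points by
construction, and a horizon beyond the last observed time is warned about
and extrapolated flat. The deliverable is the points table and risk table
(JSON/CSV), not a typeset figure.

**Calibration and discrimination.** `calibration_curve()` bins samples by
predicted survival at the horizon (quantile bins, merged below 10 samples)
and contrasts the bin-mean prediction with the bin's Kaplan-Meier estimate
and CI. `time_dependent_auc()` is the cumulative/dynamic AUC with
inverse-probability-of-censoring weights from the Kaplan-Meier estimate of
the censoring distribution; with no censoring it reduces exactly to the
Wilcoxon AUC of events-by-t versus survivors-past-t, which is tested.

# Drug sensitivity

For each subtype's cell lines: `median_split()` dichotomizes lines at the
median signature score (strictly-above = high; ties at the median go low,
deterministically), `compare_ic50()` runs a two-sided Mann-Whitney test per
drug (exact for total n ≤ 12 without ties) with direction =
sign(median high − median low), and `spearman_drug_corr()` reports Spearman
rho (average ranks, t-approximation p). Sign conventions are consistent
across the two routes: negative means higher signature expression tracks
lower ln(IC50), i.e. sensitivity. Drugs with fewer than two non-missing
lines per group are skipped with an explicit reason. ln(IC50) is assumed as
the stored scale. Tests are per-compound, unadjusted (p < 0.05), matching
the intended screening use.

# The synthetic-data generators

`simulate_counts()` draws negative-binomial UMI counts
(Var = μ + φμ², constant dispersion φ per run) with log-normal gene
baseline means (meanlog 0, sdlog 1 — a realistic UMI abundance spread
giving a few thousand UMIs per cell at 1–2k genes), log-normal cell size
factors, and disjoint planted marker sets per subtype whose means are
shifted by ±log-FC (log2 units) in that subtype's cells. Marker genes are
planted on baselines left-truncated at 1 count (`marker_min_baseline`):
a 4-fold change on a gene averaging 0.1 counts is statistically invisible
at UMI depth, and class-separation statistics select well-expressed genes
in practice — the representativeness stage measures exactly that property.
Decoy non-protein-coding and MT-/RPL-/RPS-named genes exercise the QC
filters. Centroids are the true per-subtype mean log2 expression.

`simulate_survival()` draws clinical covariates (standardized age and tumor
size, stage III indicator, therapy indicators) and a standard-normal
signature score, generates event times from a Weibull-baseline
proportional-hazards model by inverse transform (shape 1.2, scale 60
months), and tunes independent uniform censoring numerically to the target
censoring fraction (warning with the achieved rate if unattainable).
Optionally it emits a samples × genes expression matrix whose genes load on
the true score with the signature's directions, so the scoring and
stratification pipeline can be run end to end against known truth.

`simulate_cell_lines()` uses a Gaussian copula: a latent signature level
per line and one ln(IC50) vector per drug with latent Pearson correlation
2·sin(π·ρs/6), which yields the planted Spearman ρs; |ρs| = 1 is generated
exactly comonotone. The default panel is 26 lines split 6/8/4/6 across
BL1/BL2/LAR/M plus 2 unassigned, the shape of a GDSC-like TNBC extract.

All generators are pure functions of (config, seed): they save and restore
the caller's RNG state and reproduce bit-identically.

## What the generators do not emulate

Batch effects, doublets, ambient RNA, gene-gene co-expression modules
beyond the planted markers, per-gene dispersion variation, informative
censoring, and non-proportional hazards. Passing tests therefore certify
the pipeline's statistical machinery under its stated assumptions — not
robustness to the full messiness of real cohorts.

# Numerical choices and degenerate inputs

- Deconvolution: reference genes require mean count ≥ 0.1; the normal
  equations carry a 1e-8 ridge; non-positive solutions trigger the
  library-size fallback with a warning and a flag.
- Ranking ties (CM1 selection): lexicographic gene id. Classification ties:
  first subtype in declared order, warned.
- Rank-sum tests: exact only when group sizes permit and no ties; the
  identical-values degenerate case returns p = 1 by convention.
- Entropy: a constant vector occupies one bin, entropy 0; bins are
  recomputed on each vector's own range, making the estimator invariant to
  affine rescaling.
- Cutpoint search: thresholds are the observed score values; `minprop`
  bounds both group sizes; all-identical scores are an error.
- Cox fits: Efron ties, convergence tolerance 1e-11, max 50 iterations;
  monotone-likelihood warnings are promoted to errors.

# Problem sizes used in the packaged checks

The packaged test-and-verification runs use 4 × 300 cells × 2,000 genes for
marker-recovery closed loops (20 seeds), 500 cells for size-factor recovery
(6,000 genes for the tail-error bound, where per-cell error concentrates),
n = 500 with 200 replicates for hazard-model recovery, n = 300 with 20
seeds for cutpoint recovery, and 1,000 replicates for rank-sum calibration.
These sizes were chosen so each property estimate is stable at the asserted
threshold while the whole suite stays comfortably interactive.

# Known limitations

- The naive post-selection log-rank p after cutpoint optimization is
  anti-conservative by design of the convention it mirrors; a
  selection-adjusted p is out of scope.
- The signed z-mean risk score presumes roughly symmetric per-gene
  informativeness; PC1 mode is available when one gene dominates.
- The entropy estimator is the plug-in histogram estimator; it is biased
  downward at small cell counts, identically for signature and background
  genes, so the *comparison* is fair even where the absolute value is not.
- Centroid classification assumes the centroid matrix and query share a
  meaningful gene scale; no cross-platform harmonization is attempted.
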