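---
title: "Methods: the immune cell infiltration landscape workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the immune cell infiltration landscape workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iciscape)
```

## Overview

`iciscape` implements a complete immune cell infiltration (ICI) landscape
analysis for bulk tumor expression cohorts. The workflow mirrors how such
studies are conducted in practice: expression from several cohorts is put on
a common scale and batch-adjusted; per-sample immune cell fractions are
estimated by reference-based deconvolution; samples are grouped into ICI
subtypes by resampled consensus clustering; subtype-differential genes are
split into two opposing signatures; each sample receives an ICI score
(first principal component of signature A minus that of signature B); and
the score is evaluated against survival, tumor mutational burden (TMB),
pathway enrichment, and predicted drug sensitivity.

Because the cohorts such analyses are usually built on are access-controlled,
the package ships a synthetic-cohort generator that plants every structure
the downstream stages rely on, with the planted truth recorded so that each
stage can be tested quantitatively.

## The synthetic cohort generator

`simulate_cohort()` draws, in order:

1. **Cell fractions.** Per sample, a Dirichlet draw whose concentration
   vector depends on the sample's subtype, so subtypes can differ in immune
   composition when desired. Fractions lie on the simplex exactly.
2. **Expression.** Signature genes are exact linear mixtures
   `signature_matrix %*% fractions`; additional genes carry a log-normal
   baseline with a `subtype_effect` log2 mean-shift planted in
   `n_signature_genes` disjoint genes per subtype. Batch location/scale
   effects are applied on the log2 scale, then Gaussian log2-scale noise
   (`noise_sd`), i.e. log-normal noise on the linear scale — chosen because
   every downstream stage (clustering, moderated t, PCA) operates on log2
   values.
3. **Survival.** Exponential event times with per-sample hazard
   `baseline_hazard * exp(risk)`, where risk is the subtype log-hazard plus
   a small jitter. Censoring times are exponential with the rate tuned so
   each sample is censored with probability `censor_rate`, independent of
   its hazard; `censor_rate = 0` therefore yields a fully observed cohort.
4. **Mutations.** Per-sample non-silent counts are Poisson through a
   Gaussian copula against the planted risk score. The latent correlation
   uses the exact inversion `rho_g = 2 sin(pi rho_s / 6)` so the realized
   Spearman correlation matches `tmb_score_rho`; a roughly 10% admixture of
   silent records exercises the TMB filters.

One global `seed` drives everything through `spawn_seed(seed, stream)`,
a fixed affine spawning scheme, so any stage can be rerun in isolation and
reproduce the full-run draw.

**Defaults as study conditions.** The defaults describe a two-cohort
gastric-cancer-sized meta-analysis: 854 samples in batches of 407 and 447,
22 cell types, three subtypes, 84 signature genes per subtype (a DEG pool of
252), `subtype_effect = 2` and `noise_sd = 0.5`, 60% censoring, a baseline
hazard putting median survival near 4.5 years, and `tmb_score_rho = -0.52`.

**What the generator does not emulate.** Read-level sampling noise,
gene–gene correlation beyond the planted blocks, copy-number or methylation
structure, and cell-type-specific expression changes (the mixture profiles
are fixed). Passing tests therefore demonstrate correctness of the
algorithms under the stated generative model, not performance on real
tumors.

## Deconvolution

`deconvolve()` estimates fractions by nu-support-vector regression with a
linear kernel against a standardized signature matrix, sweeping
`nu in {0.25, 0.5, 0.75}` and keeping the lowest-RMSE fit, then clamping
negative coefficients and renormalizing to the simplex. Two numerical
choices matter:

* **Per-sample z-scoring** shifts and rescales the linear mixing system, so
  fit quality (RMSE, correlation) is judged after an affine alignment of
  the projected fit, and an intercept is included wherever the system is
  re-solved.
* **Least-squares polish.** The SVR solver's tolerance limits coefficient
  accuracy to about 1e-3. After the SVR identifies the active cell types,
  the coefficients are re-solved by ordinary least squares on that support
  (pruning any coefficient the polish drives negative). On noiseless
  mixtures this recovers fractions to machine precision; on noisy data it
  removes solver-tolerance jitter without changing the support decision.

The permutation p-value follows the deconvolution convention: null mixtures
are drawn without replacement from the pooled mixture values ("random gene
relabelings"), the full fit is rerun, and the p-value is the smoothed
fraction of null fit correlations at least as large as the observed one.
For a single-sample mixture the null is a pure permutation of the observed
values, which makes the p-value exchangeable-uniform by construction. When
the simplex projection degenerates (all coefficients clamped), diagnostics
fall back to the raw SVR projection so the null distribution has no tie
atom.

The expression scale question (linear vs log input) is resolved as: linear
scale for deconvolution, log2 for everything rank- or variance-based
(ssGSEA, clustering, moderated t, PCA).

## Microenvironment scores

`ssgsea_score()` is the classical single-sample enrichment statistic: genes
are ranked within the sample, and the score sums, over all rank positions,
the weighted in-set empirical CDF (weights `rank^0.25`) minus the out-set
ECDF. The score is not divided by the gene count, matching the reference
implementation's convention. `estimate_scores()` applies it to a stromal
and an immune set; the combined score is their exact sum. The stromal and
immune sets are user inputs (GMT); the package does not ship proprietary
lists and does not implement the microarray-specific nonlinear tumor-purity
transform.

## Consensus clustering

`consensus_cluster()` subsamples 80% of items per repetition, clusters each
subsample hierarchically (Euclidean distance, Ward linkage, `ward.D2`), and
records pairwise co-clustering frequencies among co-sampled pairs. Final
labels at each k come from Ward clustering of `1 - consensus`. The number
of clusters is chosen by minimum PAC — the proportion of consensus entries
in (0.1, 0.9) — with ties broken toward smaller k; consensus CDFs per k are
also returned for inspection. Item resampling only (no feature resampling),
matching common usage of the resampled-consensus approach.

The ICI subtype clustering in `run_pipeline()` uses the deconvolved
cell-fraction columns as features, without appending the
stromal/immune scores (configurable); the source protocol is ambiguous on
this point, and fractions alone keep the feature scale homogeneous.

## Differential expression and signatures

`moderated_t_degs()` performs one-vs-rest contrasts per subtype with an
empirical-Bayes moderated t: per-gene pooled variances are shrunk toward a
common prior via `(d0 s0^2 + dg sg^2) / (d0 + dg)`, with `(d0, s0^2)`
estimated by the method of moments on the log variances (numerically
identical to the standard limma estimator; when the observed log-variance
dispersion does not exceed the sampling dispersion the prior df is infinite
and the prior variance is the pooled mean). `d0` can be fixed explicitly;
`d0 = 0` reproduces the ordinary two-sample t exactly, which is the
regression test anchoring the implementation. BH adjustment is applied
within each contrast, not pooled.

A gene is differential when `p_adj < 0.05` **and** `|log2 FC| > 1`. The
"fold-change > 1" cutoff is read on the log2 scale: on the linear scale
every gene with any difference would pass, so the log2 reading is the only
internally consistent one.

The DEG union is clustered (genes as items, k = 2) with the same consensus
machinery, and samples are likewise consensus-clustered on DEG expression
into two groups. `partition_signatures()` assigns each gene cluster to
signature A or B by which sample group expresses it more highly; swapping
the sample groups swaps the signatures, and an error is raised if both gene
clusters track the same sample group.

## ICI scoring

`ici_score()` computes, per signature, the first principal component of the
gene-standardized expression (samples as observations). The "sum of PC1"
construction is interpreted as the per-sample PC1 score — one component per
signature — because summing loadings would produce a single cohort-level
number rather than a per-sample score; this is the gene-expression-grade-
index convention the construction descends from. PCA sign is arbitrary, so
each component is oriented to correlate positively with its signature's
mean expression. The score is `pc1_a - pc1_b`, exactly antisymmetric under
signature swap.

`boruta_select()` optionally reduces the signatures first: shadow features
(permuted copies) are appended, a random forest ranks permutation
importance, features beating the best shadow score a "hit", and a two-sided
binomial test at `alpha = 0.01` confirms or rejects. Features undecided
after `max_iter` iterations are tentative and excluded. The response
variable is the two-level sample gene-cluster label (configurable to the
ICI cluster), since the procedure's aim is to keep genes that carry the
signature distinction.

`dichotomize()` scans all cutpoints leaving at least `minprop = 0.1` of
samples on each side, computing the standardized log-rank statistic
`(O - E)/sqrt(V)` at each admissible midpoint, and keeps the maximizing
cutpoint (ties toward the lower value). A permutation-corrected p-value for
the selected maximum is available because maximal selection inflates the
naive log-rank p.

## Survival analysis

Kaplan-Meier estimation and the log-rank test delegate to the standard
survival machinery (deaths precede censorings at tied times).
`stratified_km()` crosses two factors (e.g. TMB group by score group),
drops empty strata with a warning, and reports per-stratum curves, medians,
and the overall log-rank test. `time_dependent_auc()` implements the
cumulative-case / dynamic-control AUC with inverse-probability-of-censoring
weights from the censoring Kaplan-Meier curve (left limits for cases);
times with no cases or no controls return NaN with a warning. The
incident/dynamic variant and Cox modelling are out of scope.

At very small n the asymptotic chi-square log-rank p deviates from the
exact permutation null by a few percent; the test suite compares the two on
an 8-sample cohort at that realistic tolerance.

## Mutation analysis

`read_maf()` parses minimal Mutation Annotation Format (three required
columns, `#` comments skipped, exact duplicates dropped, unknown
classification values kept with a warning). `compute_tmb()` counts
non-silent variants (excluding Silent, Intron, 3'UTR, 5'UTR, IGR, RNA) and
reports both the raw count and a per-megabase rate (38 Mb capture default,
since TMB units are often left undefined in study reports).
`spearman_corr()` is Pearson on mid-ranks with a t-approximation p; it
accepts n >= 3 so the classic three-point hand example is computable.
`gene_freq_contrast()` builds a mutated-by-group 2x2 table per gene and
applies the Yates-corrected chi-square (the convention consistent with
published tables of this analysis type), falling back to Fisher's exact
test when an expected cell drops below 1.

## Enrichment

`gsea_preranked()` is the classical running-sum statistic with
`|score|^weight` in-set increments, gene-label permutation nulls (set
membership reassigned at random), sign-matched NES normalization, and
+1-smoothed p-values; FDR is BH across sets rather than the signed-null
FDR of the desktop implementation — simpler and stated here openly.
Phenotype permutation is not implemented because the ranking input is
already a per-gene statistic. For score-based rankings the pipeline uses
each gene's Spearman correlation with the ICI score.
`ora_hypergeometric()` is the upper-tail hypergeometric test within a
user-stated universe. Gene-set databases are never fetched; all sets come
from user GMT files.

## Drug-sensitivity prediction

`fit_drug_model()` ridge-regresses log IC50 (natural log, micromolar) on
gene-standardized reference expression, selecting the penalty by
cross-validated MSE with a seed-deterministic fold split. Prediction
standardizes with the training parameters, imputes missing training genes
at zero (the training mean), and errors below 50% gene overlap.
Cross-cohort homogenization (batch adjustment between reference and test
cohorts) can be applied via the preprocess module but is off by default for
same-distribution synthetic tests. Named drugs are labels only; no external
sensitivity database is shipped or required.

## Pipeline

`run_pipeline()` executes the stages in order, writes plain-text artifacts
plus a manifest with parameters, seeds, and per-file md5 checksums, and is
bit-identical on rerun with the same config. Stage parameters default to
the protocol values (1000 deconvolution permutations, 1000 consensus
repetitions at 80% subsampling, k = 3 ICI clusters, k = 2 gene clusters,
adjusted p < 0.05 with |log2 FC| > 1, minprop 0.1, 38 Mb capture,
evaluation at 1/3/5 years); any value can be overridden in the config. The
examples and tests scale the resampling counts down (about 100-200
repetitions, 20 permutations) — problem sizes chosen so that the full suite
exercises every stage on cohorts of 60-200 samples.

## Known limitations

* The deconvolution p-value shares one permutation null across the samples
  of a call; p-values across samples are therefore correlated (each is
  still marginally valid).
* PAC-based k selection is a heuristic; strongly nested structure can
  prefer the coarser split.
* The IPCW AUC assumes censoring independent of the marker.
* Boruta confirmation depends on random-forest importance; with very few
  trees the hit process is noisy, so `num_trees` should stay at a few
  hundred for real use.
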