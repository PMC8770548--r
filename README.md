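# iciscape

Immune cell infiltration (ICI) landscape analysis for bulk tumor
transcriptomics.

Tumor cohorts — gastric cancer being the motivating case — are heterogeneous
in how immune and stromal cells infiltrate the tumor microenvironment, and
that heterogeneity tracks prognosis and therapy response. `iciscape`
implements the full analysis such studies run, as a tested R package:

1. **Preprocess** — FPKM→TPM conversion, log2 transform, and empirical-Bayes
   batch adjustment (ComBat) across cohorts.
2. **Infiltration** — per-sample immune cell fractions by nu-SVR
   deconvolution against an LM22-like signature matrix (with permutation
   p-values), plus ssGSEA stromal/immune/combined microenvironment scores.
3. **Subtypes** — resampled consensus clustering (Euclidean, Ward) of the
   infiltration profiles; the cluster number is chosen by minimum PAC.
4. **Signatures** — one-vs-rest moderated-t differential expression
   (adjusted *p* < 0.05, |log2 FC| > 1), consensus gene clustering, and
   partition of the DEGs into opposing signatures A and B.
5. **ICI score** — per sample,
   `ICI score = PC1(signature A) − PC1(signature B)` on gene-standardized
   expression, optionally after Boruta feature reduction; dichotomized at
   the maximally selected log-rank cutpoint.
6. **Evaluation** — Kaplan-Meier / log-rank survival comparisons, stratified
   TMB × score analysis, IPCW time-dependent ROC AUC, Spearman score–TMB
   association, per-gene mutation-frequency contrasts (Yates chi-square),
   preranked GSEA and hypergeometric over-representation, and ridge-based
   drug-sensitivity (log IC50) prediction with Wilcoxon group comparisons.

Access-controlled cohorts are not required anywhere: the package ships a
synthetic-cohort generator (`simulate_cohort()`) that plants cell-type
mixtures, expression subtypes, batch effects, survival hazards, and
score-coupled mutation counts, recording all ground truth for validation.

## Worked example

```r
library(iciscape)

cfg <- simulation_config(n_genes = 500, n_celltypes = 6, n_samples = 120,
                         subtype_effect = 2.5, noise_sd = 0.5,
                         n_signature_genes = 30, batch_sizes = c(60, 60),
                         batch_additive = c(0, 1.5), censor_rate = 0.4,
                         seed = 42)
cohort <- simulate_cohort(cfg)
#> synthetic_cohort: 500 genes x 120 samples, 3 subtypes, 2 batches

lg <- combat_adjust(log2_transform(cohort$expression), cohort$batch_labels)
fr <- deconvolve(cohort$expression, cohort$signature_matrix,
                 n_perm = 100, seed = 1)
cc <- consensus_cluster(fr$fractions, k_range = 2:5, n_reps = 200, seed = 2)
#> consensus_result: 120 items, k in {2,3,4,5}, chosen k = 3 (PAC 0.097)
ici <- consensus_labels(cc, 3)

degs <- moderated_t_degs(lg, cohort$subtype_labels)
deg_expr <- lg$values[deg_union(degs), ]
part <- partition_signatures(
  deg_expr,
  gene_cluster(deg_expr, k = 2, n_reps = 100, seed = 3),
  consensus_labels(consensus_cluster(t(deg_expr), k_range = 2,
                                     n_reps = 100, seed = 4), 2)
)
sc <- dichotomize(ici_score(lg, part), cohort$survival)
logrank_test(cohort$survival, sc$group)
#> $chi2 12.41, $df 1, $p 0.000427
time_dependent_auc(sc$ici_score, cohort$survival, c(1, 3, 5))
#>     1     3     5
#> 0.669 0.655 0.635
tmb <- compute_tmb(cohort$maf, samples = sc$sample_id)
spearman_corr(sc$ici_score, tmb$n_nonsilent)
#> $rho -0.277, $p 0.0022
```

The consensus step recovers the three planted subtypes (PAC minimum at
k = 3), the score's HIGH/LOW split separates survival (log-rank
p = 4.3e-4), the time-dependent AUCs quantify prognostic discrimination at
1/3/5 years, and the score is negatively correlated with mutation count as
planted. The full workflow is also available as one call:

```r
run_pipeline(list(seed = 11, simulate = list(n_samples = 200)), "artifacts/")
```

which writes per-stage TSV artifacts and a `manifest.json` with parameters
and md5 checksums (reruns are bit-identical).

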