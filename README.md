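# arscore — rank-based pathway activity scoring and co-regulation analysis

`arscore` quantifies the activity of biological pathways (gene sets) in
individual expression profiles and analyses how that activity is organised
and perturbed across samples.  It is aimed at anyone working with bulk
microarray or RNA expression matrices — classically tumor-vs-normal
compendia — who wants pathway-level, single-sample statistics that are
robust to normalization differences between datasets.

## The statistic

For one sample, rank all `n` measured genes by relative expression
(mid-ranks for ties, rank `n` = most highly expressed).  A pathway with
`m` measured members gets the **AR-score** (average-rank score)

    AS = (r_1 + ... + r_m) / (m * n)

a value in (0, 1]: near 1 when the pathway's genes crowd the top of the
ranking, near 0 when they sink to the bottom.  Being rank-based, the score
is invariant under monotone transforms of a sample's values and directly
comparable across pathways, samples and datasets.  Around this statistic
the package implements:

* **Scoring** — AR, an absolute-value AR variant for two-channel
  log-ratios, and a KS-like enrichment score (ES) as comparator
  (`activity_matrix`, `ar_score`, `es_score`).
* **Co-regulation networks** — Spearman correlation of activity profiles
  for all pathway pairs *with shared genes excluded*, thresholded at
  |rho| > tau (`pathway_cor`, `build_network`), plus condition
  comparisons of coupling strength (`compare_coupling`).
* **Differential activity** — per-pathway Welch t or Wilcoxon tests with
  Storey q-value FDR control (`t_test_pathways`, `wilcoxon_pathways`,
  `storey_qvalue`), direction summaries (`fraction_upregulated`) and
  cross-dataset consistency (`tscore_consistency`).
* **Within-pathway co-expression** — mean pairwise Spearman correlation of
  member genes (`pathway_coexpression`, `compare_coexpression`).
* **Clustering & classification** — complete-linkage clustering and
  leave-one-out cross-validated linear SVM with leak-free per-fold pathway
  selection (`hier_cluster`, `select_pathways`, `loocv_classify`).
* **Synthetic data** — a Gaussian factor model with known ground truth
  (coupling, co-expression, planted differential pathways, overlapping
  sets) so the whole pipeline is testable offline (`sim_config`,
  `simulate_expression`).

Input formats: TSV or GCT 1.2 expression matrices, GMT gene sets,
two-column TSV labels.  A command line (`inst/cli/arscore.R`) exposes the
pipeline as subcommands (`score`, `correlate`, `network`, `diff`,
`coexpr`, `classify`, `cluster`, `simulate`).

## Worked example

Simulate a 40-sample tumor/normal study (100 pathways, 10 of them shifted
up by 1 sd in tumors), score it, and run the downstream analyses:

```r
library(arscore)
cfg <- sim_config(n_samples = c(normal = 20, tumor = 20), seed = 42)
sim <- simulate_expression(cfg)

z    <- standardize_genewise(sim$expression)     # per-gene z-scores
sets <- restrict_to_matrix(sim$sets, z)$sets
act  <- activity_matrix(z, sets, "AR")           # 100 pathways x 40 samples

round(act[1:3, 1:4], 3)
#>       normal_01 normal_02 normal_03 normal_04
#> pw001     0.545     0.652     0.261     0.254
#> pw002     0.455     0.673     0.561     0.303
#> pw003     0.483     0.346     0.291     0.165

dt <- t_test_pathways(act, sim$labels, groups = c("tumor", "normal"))
print(dt, n = 3)
#> Differential pathway table: 100 pathways, groups tumor vs normal
#> (direction 'up' = higher in tumor), pi0 = 0.683
#>   pathway mean_tumor mean_normal         t            p direction            q
#> 1   pw006  0.6577972   0.3372454 11.441837 8.195623e-14        up 5.601558e-12
#> 2   pw008  0.6418443   0.3566063  9.972734 3.685378e-12        up 1.259444e-10
#> 3   pw005  0.6307019   0.3606712  7.520623 5.913820e-09        up 1.347329e-07
sum(dt$q < 0.01)        # exactly the 10 planted pathways at 1% FDR
#> [1] 10

pc  <- pathway_cor(sets, z[, sim$labels == "normal"])  # shared genes excluded
net <- build_network(pc, tau = 0.75)
print(net)
#> Pathway co-regulation network (|rho| > 0.75): 100 nodes, 1 edges (1 positive, 0 negative)

loocv_classify(act, sim$labels, selection_mode = "per_fold", p_cut = 1e-4)
#> Leave-one-out SVM classification (linear kernel, C = 1, per_fold pathway selection)
#>   40 samples, accuracy = 1.000 (40 correct)
```

The AR-scores of the ten planted pathways rise from ~0.36 in normals to
~0.64 in tumors; all ten (and only those) pass the 1% FDR cut, and the
per-fold-selected SVM separates the groups perfectly.

## The methods vignette

`vignettes/pathway-activity.Rmd` documents the model and its assumptions,
the preprocessing rationale, the shared-gene exclusion, the Storey
estimator, the generator design and its deliberate simplifications, and
all numerical edge-case policies.
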