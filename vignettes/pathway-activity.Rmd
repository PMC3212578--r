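---
title: "Rank-based pathway activity: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based pathway activity: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arscore)
```

## The activity statistic

Given one sample's expression profile over $n$ genes, rank the genes by
relative expression with mid-ranks for ties, assigning rank $n$ to the most
highly expressed gene.  The activity of a pathway with $m$ measured members
is the normalized average rank

$$AS \;=\; \frac{1}{m\,n}\sum_{i=1}^{m} r_i ,$$

where $r_i$ is the rank of the $i$-th member.  $AS$ lies in $(0,1]$ with
bounds $[(m+1)/2n,\;(2n-m+1)/2n]$; values near 1 mean the pathway's genes
crowd the top of the sample's ranking.  Because only ranks enter, the score
is invariant under any strictly monotone transform of a sample's values,
hence robust to incomplete normalization, and directly comparable between
pathways of different sizes and between samples from different datasets.

Two assumptions are worth keeping in view.  First, activity is equated with
the *relative mRNA abundance* of member genes; pathways regulated mainly
post-translationally, or driven by repressors whose transcripts fall when
the pathway activates, are scored poorly by construction.  Second, the
score averages ranks, so a pathway in which half the members rise and half
fall reads as unchanged.  For two-channel log-ratio data the package offers
the absolute-value variant (`score_type = "AR_abs"`), which ranks $|z|$ so
that strong movement in either direction raises the score.

As a comparator the package also computes the Kolmogorov–Smirnov-style
enrichment score: walking the ranked list from top to bottom, member hits
add $1/m$ (or $|z_i|/\sum|z|$ when weighted), misses subtract $1/(n-m)$,
and the score is the running sum at its largest absolute excursion, signed.
On exchangeable data the AR-score is approximately normal while the ES is
bimodal (one positive and one negative peak), which is why downstream
comparisons use the t-test for AR-scores but the Wilcoxon rank-sum test for
ES-scores.  The unweighted walk is the default; weighting is available by
flag since conventions differ between implementations.

## Preprocessing

One-channel intensities are converted to relative levels gene-wise:
subtract each gene's mean and divide by its standard deviation across
samples (sample sd, $n-1$ denominator — the conventional choice for
microarray z-scoring; with at least two samples either denominator leaves
the within-sample ranking identical).  Ranking a raw intensity column would
largely reproduce the platform's probe-brightness order; ranking the
z-scored column orders genes by how unusually high they are *in this
sample*, which is what "activity" means here.  The test suite includes a
fixture where skipping standardization demonstrably changes the scores.
Zero-variance genes carry no relative information and are dropped with a
warning.  Two-channel log-ratios are already relative and bypass the step
(`--standardize off`).  Gene sets are intersected with the matrix rows, and
sets with fewer than `min_genes` (default 5) mapped members are excluded:
the average of a couple of ranks is too unstable to call a pathway score.

## Pathway co-regulation networks

The similarity of two pathways' activity is the Spearman correlation of
their AR-score profiles across samples.  Shared member genes would let a
pair correlate with itself, so the intersection is removed first and both
profiles recomputed on the residual (unique) members; pairs whose residual
set falls below `min_genes` are reported *not evaluable*, never as zero.
For $K$ pathways all $K(K-1)/2$ unordered pairs are evaluated — 17,205 for
a 186-pathway collection.  A network connects pairs with $|\rho| > \tau$
(strict inequality; default $\tau = 0.75$), keeping isolated pathways as
nodes annotated with their gene counts.  Coupling between conditions is
compared over the common pair universe with a paired t-test on absolute
coefficients by default: the pairs are matched entities across conditions,
and absolute values measure coupling strength irrespective of direction.
Signed mode and an unpaired Welch test are available, since either
convention is defensible for specific questions.

## Differential activity and FDR

Per pathway, activity is compared between two groups with a two-sided
Welch t-test (the safer default when group variances differ, as they do in
tumor/normal designs).  Multiplicity is controlled with Storey q-values:
$\hat\pi_0(\lambda) = \#\{p > \lambda\}/(m(1-\lambda))$ is computed on
$\lambda = 0.05, 0.10, \dots, 0.95$, smoothed with a cubic smoothing
spline (3 df), read off at $\lambda = 0.95$ and clipped to $(0,1]$; then
$q_{(i)} = \min_{j \ge i}\, \hat\pi_0\, m\, p_{(j)}/j$, which equals the
Benjamini–Hochberg adjustment scaled by $\hat\pi_0$ and is enforced
monotone in $P$.  The smoother variant was chosen over the bootstrap
because it is deterministic given the p-values.  Pathways with $Q < 0.01$
(1% FDR) are called differential by convention; the CLI exposes the cut.
Direction "up" means higher mean activity in the first group.

Two descriptive companions: `fraction_upregulated()` reports, per pathway,
the share of member genes with gene-level $t > 0$, overall and among
members with $P$ below a cut (default 0.001) — fractions near 0 or 1 show
that a pathway's perturbation is directionally coherent; and
`tscore_consistency()` correlates the t-score vectors of two independent
datasets, where pathway-level statistics are expected to replicate better
than gene-level ones because averaging over members cancels
sample-specific gene noise.

## Co-expression, clustering, classification

Within-pathway co-expression is the mean of all $m(m-1)/2$ pairwise
Spearman coefficients of member expression profiles, computed on
pairwise-complete samples; pairs with fewer than 3 complete samples are
dropped rather than imputed.  Sample clustering uses complete linkage on
Euclidean distances of activity profiles.  Classification is a
linear-kernel SVM (cost $C = 1$; no kernel or parameter search — the
features are already commensurate scores in $(0,1)$, so no re-scaling
either) evaluated by leave-one-out cross-validation.  Discriminating
pathways can be pre-selected globally before cross-validation — the
historically common procedure, which leaks the test sample into feature
selection — or re-selected inside every training fold (`per_fold`, the
default).  Both modes are reported explicitly and a dedicated test plants a
spurious signal in the held-out sample only and asserts per-fold selection
is unchanged.

## The synthetic generator

Real tumor/normal compendia cannot be bundled, so every claim is exercised
on a Gaussian factor model with known truth.  Per condition, each sample
carries a global factor $g$; pathway $k$'s latent activity is
$a_k = \sqrt{\gamma}\, g + \sqrt{1-\gamma}\, u_k$, so all pathway latents
share exchangeable correlation $\gamma$ — a deliberately broad coupling,
mirroring the dense co-regulation observed among pathways in normal
tissue.  A member gene is $\sqrt{\rho_w}\, a_k + \sqrt{1-\rho_w}\,
\varepsilon$, giving within-pathway gene correlation $\rho_w$ and unit
marginal variance; background genes are pure noise; a per-gene baseline
(mean 8, sd 2, constant across samples) emulates absolute intensities and
is removed by standardization.  This construction is positive semi-definite
for any $\gamma, \rho_w \in [0,1)$, so infeasible configurations cannot
arise silently.  Differential pathways shift their members' means by
$\delta$ in the second condition, expressed in marginal-sd units — the
shift is applied at the gene level so that $\delta$ and $\rho_w$ remain
independent knobs (a latent-level shift would realize as
$\sqrt{\rho_w}\,\delta$ and conflate them).  Designated pathway pairs
share a configured fraction of members purely to exercise the shared-gene
exclusion logic.  Gaussian margins suffice because every downstream
statistic is rank- or t-based; only the correlation and mean structure
matters.

Defaults describe a modest two-group microarray study: 4,000 genes, 100
pathways of 10–30 genes, 30 samples per group, $\rho_w = 0.3$ (normal)
attenuated to $0.15$ (tumor) — typical mean within-pathway correlations in
tissue compendia run 0.2–0.4, with extremes like ribosomal sets near 0.8 —
$\gamma = 0.6$ attenuated to $0.2$, ten differential pathways at $\delta =
1$.  What the generator does *not* emulate: probe-level effects, batch
structure, heavy-tailed noise, pathway-size-correlated expression, and
curated-set redundancy beyond the explicit overlaps.  Tests passing on
this model therefore validate the statistics and their implementation, not
performance on any particular real dataset.

One subtlety the model exposes: because ranks are within-sample relative
measures, coupling carried by a global factor partially cancels out of the
rank profiles when pathway members dominate the gene universe.  The
coupling-recovery checks therefore keep pathway genes a small fraction of
all genes, as they are in real platforms (a few thousand pathway genes on
a ~20,000-gene array).

## Numerical choices and degenerate inputs

Mid-ranks for ties (preserves the rank-sum identity $\sum r_i =
n(n+1)/2$); ES extremum ties resolved to the earliest position in the
walk; single-member sets may reach the boundary score 1, accepted as
valid; per-sample $n$ recomputed when missingness differs between samples;
a pathway with no measurable member in a sample yields `NA`, never 0;
paired comparisons of identical inputs (zero-variance differences) return
$t = 0$, $P = 1$ rather than erroring; $\hat\pi_0$ is clipped into
$(0,1]$; edge lists are written with lexicographically ordered pairs and
output headers omit timestamps so reruns are byte-identical.

## Problem sizes used in the checks

The bundled verification uses sizes chosen to make each effect decisively
detectable at desk scale: exhaustive AR oracles at $n \le 8$, $m \le 4$;
coupling recovery with 50 pathways × 100 samples per condition;
co-expression recovery with 100 pathways × 200 samples; differential
recovery with 10 planted pathways among 100 over 20 replicates; LOOCV on
40 samples.  Larger designs change nothing qualitatively; they only
sharpen the same estimates.

## Known limitations

The AR-score inherits the limitations discussed above (transcription-only
view, cancellation of mixed-direction regulation, no variance term — one
could weight by the dispersion of member ranks).  Spearman p-values, where
shown, use the t-approximation with $p-2$ degrees of freedom and depend on
sample count; network edges should be read as exceeding the chosen $\tau$,
not as significance calls.  Global pre-selection of classifier pathways
inflates LOOCV accuracy and is provided only for comparability with the
older procedure.
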