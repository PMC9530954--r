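---
title: "Methods: consensus subtyping of multi-batch AD expression cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus subtyping of multi-batch AD expression cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(adsubtype)
```

This vignette records the statistical models the package implements, the
assumptions behind them, the parameters a user may want to move, and the
design decisions taken where several defensible choices existed. It states no
empirical result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The analysis chain

The package targets one recurring study design: bulk expression matrices
(log2 scale, genes × samples) pooled from several microarray batches or
platforms, each sample labelled AD (case) or ND (non-demented control) and
annotated with clinical traits (CDR, Braak stage, neurofibrillary tangle
density, CERAD score, neuritic plaque density, tissue pH, age, sex). The
pipeline runs: batch correction → AD/ND differential expression → consensus
clustering of AD samples → subgroup signatures → GSEA and hub genes →
clinical-trait association → exhaustive diagnostic-panel search on held-out
samples.

## Empirical-Bayes batch correction

**Model.** For gene $g$, sample $j$ in batch $i$:
$Y_{ijg} = \alpha_g + X\beta_g + \gamma_{ig} + \delta_{ig}\,\varepsilon_{ijg}$,
$\varepsilon \sim N(0, \sigma_g^2)$ — additive and multiplicative batch
effects on top of a gene-level grand mean and protected covariates $X$.
Estimation proceeds in the standard three steps: least-squares
standardization (with the grand mean defined as the batch-size-weighted
combination of batch means, so $Z$ has pooled mean 0 and pooled variance 1
per gene), empirical-Bayes shrinkage of per-batch location/scale estimates
toward batch-level priors ($\gamma_{ig} \sim N(\bar\gamma_i, \bar\tau_i^2)$,
$\delta^2_{ig} \sim \mathrm{InvGamma}(\bar\lambda_i, \bar\theta_i)$,
hyperparameters moment-matched across genes within each batch), and
adjustment that removes $\gamma^*,\delta^*$ and restores the grand
parameters.

**Numerical choices.** The two coupled posterior equations are solved by
fixed-point iteration with relative tolerance `1e-4` and a cap of 100
iterations (warning on cap); the tolerance is far below anything downstream
tests can resolve, and the converged values satisfy both equations to
`1e-6` when substituted back (asserted in the test suite). Inverse-gamma
moment matching uses $\bar\lambda = (2s^2+m^2)/s^2$,
$\bar\theta = (ms^2+m^3)/s^2$ for the across-gene mean $m$ and variance
$s^2$ of $\hat\delta^2_{ig}$. Degenerate priors (zero across-gene variance)
fall back to no shrinkage for that batch, with a warning. Genes with zero
pooled variance cannot be standardized; they are excluded from the model and
passed through unchanged. With `eb = FALSE` the correction reduces exactly
(to `1e-8`) to per-batch location/scale standardization restored to the
pooled scale — the oracle used in tests.

**Protected covariates.** By default the AD/ND condition indicator enters
$X$, so disease signal is not absorbed into batch means. A confounded design
(condition collinear with batch) is an error, not a warning: correction
would be meaningless. Covariate-free mode is available.

**Verification of removal.** `batch_check` reports the share of variance of
the first two principal-component scores explained by batch membership
(variance-weighted one-way ANOVA $R^2$ over PC1–PC2). This summarizes the
usual "does PCA still separate batches" visual check as one number in
$[0,1]$.

## Consensus subtyping

AD samples are clustered for each $K = 2..K_{\max}$ ($K_{\max} = 10$ by
default) by drawing `n_resamples = 100` subsamples of
`sample_fraction = 0.8` of the samples without replacement, clustering each
subsample into $K$ groups, and recording for every sample pair the fraction
of co-resampled runs in which it co-clusters (the consensus matrix $M$).
Final assignments cut an average-linkage dendrogram of $1 - M$ into $K$
groups; each cluster is scored by its mean within-pair consensus $m(k)$, and
the selected subgroup count is the **largest** $K$ whose minimum $m(k)$
exceeds 0.8 — among stable partitions, finer structure is preferred. If no
$K$ qualifies, downstream stages refuse to run without an explicit
`force_k`.

**Base clusterer.** K-means (Hartigan–Wong, one random start per resample,
seeded deterministically per resample) on samples, over genes standardized
to zero mean and unit variance — chosen for speed and determinism;
average-linkage hierarchical clustering on Pearson-correlation distance is
available via `base = "hclust"`. Resampling and clustering are driven by
sample *identities* in sorted order, so permuting the input columns permutes
the output consistently.

**A structural caveat on the selection rule.** When the case population
consists of $c$ equally sized, well-separated clusters, the rule can
qualify $K = c + 1$: every sensible base clusterer then produces a clean
"split one cluster" partition, the split cluster varies roughly uniformly,
and each within-cluster pair co-clusters in about
$\tfrac{c-1}{c} + \tfrac{1}{c}\cdot\tfrac12$ of resamples — $5/6 \approx
0.83 > 0.8$ for $c = 3$, independent of noise level or split orientation.
On synthetic cohorts with three *exchangeable* planted subtypes the rule
therefore often reports 4 subgroups (the true-K partition itself is still
recovered essentially perfectly, and its consensus is far higher, typically
$> 0.97$ versus $\approx 0.83$). Real cohorts, with unequal subtype sizes
and non-exchangeable structure, do not sit exactly at this boundary. Users
who prefer the most parsimonious stable partition should inspect the full
score table (always retained in the `consensus_selection` object) rather
than rely on the threshold rule alone; we deliberately did not alter the
rule or the threshold, which are part of the procedure being reproduced.

**Singletons.** A singleton cluster has no within-pairs; its $m(k)$ is 1 by
convention and the event is logged — a qualifying $K$ achieved via
singletons deserves scrutiny.

## Differential expression and signatures

Per gene, a two-sided Wilcoxon rank-sum test (exact when both groups have
$\le 8$ tie-free observations, otherwise normal approximation with midrank
tie correction and continuity correction), BH adjustment applied jointly
over all genes *within* each comparison, and the dual threshold: adjusted
$p < 0.05$ **and** |mean difference| $> 0.2$ log2 units, the reference-group
mean subtracted. Subgroup-specific upregulated signatures require a gene to
pass with positive effect against *every* other subgroup, which makes
signatures disjoint by construction; a pooled-rest mode exists behind a
flag. BH per comparison (not across the union of comparisons) matches how
the thresholds are phrased per contrast; the alternative would couple
unrelated contrasts through their p-value pools.

## GSEA, leading edge, hub panels

The ranked list orders genes by a signal-to-noise metric
$(\bar x_a - \bar x_b)/(s_a + s_b)$, ties broken by gene id; a group
standard deviation that is numerically zero is replaced by
$\max(0.2\,|\bar x|, 10^{-8})$ so constant genes contribute 0 rather than a
division error. A signed-t alternative exists (`metric = "t"`) because
p-value-based orderings of the same contrast are equivalent to |t| ordering;
signal-to-noise is the default because it matches the "rank metric score"
vocabulary used for hub selection. The enrichment score is the signed
extremum of the weighted Kolmogorov–Smirnov running sum (hit weight
$|r|^p/\sum_{hits}|r|^p$ with $p = 1$ by default; $p = 0$ retained for
oracle tests), the leading edge is the set members at or before (after, for
negative scores) the extremum, and hub panels take the top
$\min(10, |\text{leading edge}|)$ leading-edge genes by absolute metric.

Significance uses phenotype-label permutations (condition labels permuted
within the pooled two groups, metric and score recomputed each time), with
add-one smoothing of the nominal p (prevents $p = 0$ artifacts at finite
permutation counts), $NES = ES / \mathrm{mean}|ES_{perm,\text{same sign}}|$,
and the standard NES-ratio FDR across the evaluated collection. When the
number of distinct label splits is at most the requested permutation count,
splits are enumerated exhaustively (with a notice), making small-sample p
values exact. Over-representation of discrete gene lists against GMT
collections uses the upper-tail hypergeometric probability with BH across
sets; no gene-identifier translation or live annotation databases are
involved — gene ids match by exact string after whitespace trimming.

## Clinical association

All trait comparisons are pairwise-complete: missing trait values are
dropped per analysis, never imputed, and per-group n is reported. Pairwise
Wilcoxon rank-sum across ND and the subgroups; pooled two-proportion
chi-square (continuity correction off by default, matching the conventional
"pairwise proportion test") for the female fraction; Spearman correlations
(midranks, exact p for small tie-free n); Kruskal–Wallis with tie
correction, the all-identical degenerate case returning $H = 0, p = 1$.
The module eigengene of a gene set is the first right-singular vector of
the gene-standardized expression block, recentred to mean zero and oriented
so its mean correlation with member genes is non-negative; variance
explained is reported. Gene–trait and eigengene–trait tables default to the
AD samples of the relevant subgroup (ND samples can be included via the
caller's sample selection); significance stars follow * < 0.05, ** < 0.01,
*** < 0.001.

## Diagnostic panels

All $2^k - 1$ non-empty subsets of each subgroup's $k$-gene hub panel
($k \le 20$ guard; three 10-gene panels give 3,069 evaluations) are fitted
as logistic AD/ND classifiers by maximum likelihood on training samples and
scored by AUC (Mann–Whitney form, ties at ½ — identical to trapezoidal ROC
integration) on validation samples held out by a stratified split — never
in-sample, which would bias a best-subset search upward. On perfect
separation (detected by the glm warning, non-convergence, or a residual
deviance below $10^{-6}$) the fit falls back to a small-L2
ridge-stabilized IRLS ($\lambda = 0.01$ on non-intercept coefficients) with
a notice; rankings, hence AUC, are insensitive to the exact $\lambda$. Ties
in best-panel selection prefer smaller panels, then lexicographic order.
Interpretation bands: AUC $> 0.9$ outstanding, $0.7$–$0.9$ acceptable.

## The synthetic cohort generator

`generate_cohort` emulates the structure of a merged multi-study cohort:
per-gene baselines $N(7, 1.5^2)$ on the log2 scale; three planted AD
subtypes (equal proportions by default) each with a disjoint block of 100
marker genes shifted by `marker_effect` (default 1.0 log2) in that
subtype's samples; per-(batch, gene) additive offsets
$N(0, 0.5^2)$ and multiplicative factors $U(0.8, 1.25)$ applied to the
residual noise — exactly the location/scale model the batch correction
assumes; Gaussian residual noise with sd 1.0 (within-subtype gene-level
log2 variability of about 1 is typical of bulk brain microarray cohorts;
the choice makes planted subtypes strong but not noise-free); about 40%
control samples across three batches. Clinical traits are truncated
Gaussians (Bernoulli for sex) with subtype offsets chosen so subtypes 1 and
3 carry high CDR/Braak/NFT relative to subtype 2, plaque density is
elevated and pH lowered in all AD samples. One integer seed governs
everything through deterministically derived per-stage sub-streams.

What the generator does **not** emulate: correlated co-expression modules
(noise is independent across genes), probe-level artifacts, platform-
specific intensity distributions, missing expression values, and
non-Gaussian trait distributions. Passing recovery tests on this generator
therefore demonstrates correctness of the machinery under its stated model,
not performance on real cohorts — in particular, consensus clustering is
easier here than in practice (spherical clusters), while the
K-selection boundary effect described above is *harder* (exact
exchangeability of subtypes).

## Problem sizes and reproducibility

The test suite and acceptance script run recovery analyses at 2,000 genes,
240 AD + 120 ND samples over three batches, 100 consensus resamples for
each K up to 10, five independent seeds; calibration studies use 20
replicate null cohorts of 1,000 genes at 50 vs 50 samples; the panel search
fits all 3,069 subsets on a 70/30 stratified split of the 2,000-gene
cohort. These sizes make every stage's behavior measurable in minutes on a
single CPU while keeping test statistics (sensitivity, ARI, AUC) in the
regime where their expected values are sharp. Every pipeline output table
carries the run seed and threshold set in its header; re-running with the
same configuration and seed reproduces all outputs byte-for-byte.

## Known limitations

- Parametric priors only in the batch correction (no nonparametric mode, no
  reference batch, no missing-value EM).
- The K-selection rule's boundary behavior on exchangeable equal-size
  clusters, discussed above.
- No CDF/delta-area consensus diagnostics beyond the raw score table.
- Signature GSEA treats the discovered signatures as gene sets on the same
  cohort (train portion); this is a self-consistency check of subgroup
  separation, not independent validation — only the panel AUCs use held-out
  samples.
- No gene-identifier resolution: matrices from different sources must
  already share an identifier space.
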