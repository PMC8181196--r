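---
title: "Methods: lncRNA subtype discovery and Bayesian compound covariate classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lncRNA subtype discovery and Bayesian compound covariate classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncsubtype)
```

## The problem

Gastric tumors are clinically heterogeneous, and long non-coding RNA
(lncRNA) expression carries subtype structure that protein-coding
profiles alone do not resolve. The workflow in this package stratifies
an expression cohort into K molecular subtypes from its lncRNA profile,
ports that stratification to cohorts where only mRNA is measured via a
subtype-specific mRNA signature and a probabilistic classifier, and
then asks the downstream questions that make a stratification clinically
useful: do the subtypes differ in survival, does chemotherapy benefit
depend on subtype, how do the subtypes relate to other published
classifications, and which drugs preferentially kill cell lines with a
high membership probability for an aggressive subtype?

Because the cohorts this kind of study draws on are external accessions,
the package ships a synthetic-cohort generator that reproduces the
*statistical structure* those analyses assume. Everything downstream is
exercised, tested, and validated on generated cohorts.

## Subtype discovery

Discovery operates on the lncRNA matrix after per-gene median centering.
The `n_top = 1000` most variable genes (sample SD, lexicographic
tie-break) feed average-linkage hierarchical clustering on correlation
distance, `1 - r` between sample profiles; the tree is cut at `k = 6`.
Correlation distance with average linkage is the conventional choice for
expression-heatmap clustering; both are arguments
(`distance = "euclidean"`, `linkage = "complete"`/`"ward"`) rather than
hard-coded, because no single choice is canonical. Cut labels are
renumbered 1..K by decreasing cluster size with ties broken by the
smallest contained sample ID, which makes labels reproducible across
sample orderings — cluster *numbers* are otherwise arbitrary, and
downstream code never assumes they align with any other labeling.

`evaluate_k()` reports mean silhouette width (on the same distance) over
a K range. It is deliberately a guide, never an automatic selector: K is
a modeling decision the analyst makes and records.

## Signatures

For subtype *s*, every mRNA is tested with a one-vs-rest two-sample
t-test, pooled-variance form on `n - 2` degrees of freedom, two-sided.
The *log ratio* is the difference of group means on the log2 scale. The
signature keeps genes with raw `p < 0.001` **and** positive log ratio,
ranks by descending log ratio (gene-ID tie-break), and truncates to 200
genes. Three choices deserve comment:

* **Pooled rather than Welch variance** — the compound covariate
  classifier below weights genes by exactly these t-statistics, and the
  compound covariate tradition uses the pooled form; Welch is available
  via `var_equal = FALSE`.
* **Up-regulated genes only** — subtype signatures here are blocks of
  over-expressed genes; ranking by absolute log ratio is available via
  `direction = "abs"` for contrasts where down-regulation matters.
* **No multiple-testing correction** — the signature gate is a raw
  p-value threshold by design; the t-test's calibration (type-I fraction
  ≈ α on null cohorts at α = 0.01 and 0.001) is asserted in the test
  suite, so the expected null contamination of a signature is known.

The same machinery applied to the lncRNA matrix yields lncRNA
signatures (used, e.g., for responder-stratification GSEA); feature
space is a parameter, not a separate code path.

## The Bayesian compound covariate predictor

Each subtype gets an independent one-vs-rest binary model. A sample's
**compound score** is

> score = Σ_g  t_g · x_g

over the signature genes, with `t_g` the training t-statistic and `x_g`
the z-scored expression. On the training cohort the scores of the
in-class and out-class samples give class means μ_in and μ_out and a
pooled within-class SD σ (per-class SDs via
`shared_variance = FALSE`). The posterior for a new score is the
two-Gaussian Bayes rule

> P(in | s) = π φ(s; μ_in, σ) / [π φ(s; μ_in, σ) + (1 − π) φ(s; μ_out, σ)]

computed on the log scale so it is finite for any score. Two deliberate
choices:

* **Priors default to 0.5**, not class frequencies. In one-vs-rest with
  K = 6 the "rest" class is always ~5× larger; empirical priors would
  push every posterior toward 0. Empirical priors remain available per
  model.
* **Posteriors are not renormalized across subtypes.** Each is a
  meaningful stand-alone membership probability (downstream analyses
  correlate a *single* subtype's probability with drug response), so
  assignment is argmax of the raw one-vs-rest posteriors, ties to the
  smallest subtype index.

**Cross-cohort harmonization.** A model trained on one platform cannot
score raw intensities from another. The contract is: every cohort is
z-scored per gene *within itself* before scoring. An additive per-gene
batch shift is absorbed exactly by this transformation, which is what
the batch-shift generator + prediction tests verify. Signature genes
missing from a test platform contribute 0 (their z-scored expectation);
below 50% signature coverage the prediction errors out rather than
degrading silently.

**Validation.** `loocv_auc()` re-derives *everything* — t-tests,
signature selection, z-scoring statistics, BCCP parameters — on the
remaining n−1 samples for each held-out sample, so no leakage inflates
the posteriors. Per-subtype AUROC is the mid-rank Wilcoxon statistic of
the held-out posteriors against cluster membership. Leave-one-out was
chosen over resubstitution as the honest default for the "AUC > 0.9 for
every subtype" validation bound; `resubstitution_auc()` reports the
optimistic figure separately. The loop uses sum/sum-of-squares
downdating rather than recomputation; its exact equality (1e-10) with
the naive path is itself a test.

## Survival analysis

`km_estimate()` and `logrank_global()` implement the product-limit
estimator and the K-sample log-rank test directly from their formulas
(observed minus expected events over pooled event times; hypergeometric
variance–covariance; χ² on K−1 df via a generalized inverse when a
group's variance block is singular). Tied events are processed
simultaneously and censored observations at a tied time leave the risk
set after the events — the standard convention, stated because it
matters for reproducibility. The test suite pins both functions to the
independent `survival` package (survfit/survdiff) at 1e-8–1e-12 on
random censored samples, and checks the log-rank type-I error lands in
[0.03, 0.07] at nominal α = 0.05 over 2000 null simulations.

Pairwise subtype comparisons adjust the K(K−1)/2 log-rank p-values with
Benjamini–Hochberg by default (Bonferroni via `adjust`). Endpoint
(OS/RFS) and stage restrictions are pre-filters on the records table,
not separate code paths; `treatment_benefit()` then compares arms within
one subtype.

## Associations

* **Cross-tabulation** of two labelings over their shared samples
  produces the contingency matrix a chord diagram visualizes; rendering
  is out of scope.
* **Drug screening** correlates each drug's AUC (area under the
  dose–response curve; higher = more resistant) with per-line subtype
  probability using mid-rank Spearman ρ; two-sided p by the
  t-approximation for n ≥ 10 and the exact n! permutation null below
  that. `concordant_hits()` requires raw p < 0.05 *and* the required
  sign in **every** dataset — deliberately a per-dataset gate with no
  meta-analysis, mirroring how a two-dataset concordance call is made.
* **Pre-ranked GSEA** uses the weighted Kolmogorov–Smirnov running sum
  (hit increments ∝ |metric|^weight, default weight 1; weight 0 is the
  classical KS statistic, tested against brute force). Significance
  comes from permuting set membership over genes: with a small trial
  cohort (tens of samples) phenotype permutation is underpowered, and
  gene permutation is the standard pre-ranked fallback. NES divides the
  ES by the mean |ES| of same-sign permutations; p has the usual
  (1 + b)/(m + 1) floor.

## The synthetic generator

`generate_training_cohort()` draws subtype labels from a proportion
simplex, gives every gene an N(6, 1.5) log2 baseline, adds
N(0, noise_sd²) noise everywhere, and shifts each subtype's disjoint
marker-gene block up by `effect_size` in that subtype's samples. The
defaults — n = 300 samples, six equiprobable subtypes, 50 markers per
subtype per space, effect 2 over noise 0.5 (a 4× ratio), batch shift SD
1 — are the package's fixed study conditions: large enough for stable
signatures, small enough that the full LOOCV validation runs in
seconds. Noise is Gaussian on the log2 scale because the pipeline
consumes normalized matrices only; no count-level simulation is
attempted. Markers are up-shifted only, matching the block-upregulation
structure the signature step assumes. Treatment arms are
Bernoulli(0.5), independent of subtype. Survival times are exponential
per subtype with a multiplicative within-subtype treatment hazard
ratio, independent exponential censoring, and administrative censoring
at 120 months; drug panels couple selected drugs' AUC linearly
(negative slope) to membership probability.

What the generator does **not** emulate: gene–gene correlation beyond
the shared subtype shift, heavy-tailed or intensity-dependent noise,
partially overlapping marker programs, probe-mapping loss between
platforms, non-proportional hazards, or clinicopathological covariates.
Passing tests therefore demonstrate that the *procedures* are correct
and well-calibrated under their stated assumptions — not that real
cohorts will yield six clean subtypes.

## Numerical conventions and degenerate inputs

Sample SD (n−1) everywhere; constant genes z-score to 0 and are
flagged; zero-variance sample profiles are an error under correlation
distance; a zero-variance gene in a t-test gives t = 0, p = 1 when the
group means agree and ±Inf, p = 0 when they do not; empty signatures
warn rather than error (training on one errors); an all-censored
log-rank input is an explicit error; constant ranks give NA rows in the
drug screen rather than aborting the panel. Seeds are explicit
arguments everywhere — there is no hidden RNG state, and every
generator is bit-reproducible under a fixed seed.

## Problem sizes

The shipped analyses and tests use the default cohort (300 × 1200 lnc +
2500 mRNA genes), 10 cohort replicates for the LOOCV validation bound,
20 replicates for clustering recovery, 2000 null simulations for
log-rank calibration, and 20-seed replication for the two-panel drug
concordance check — sizes chosen so each claim is a stable median or
rate rather than a single lucky draw.
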