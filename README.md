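# lncsubtype

Molecular subtyping of tumor expression cohorts from long non-coding
RNA (lncRNA) profiles, with a Bayesian compound covariate predictor
(BCCP) that carries the subtypes to cohorts where only mRNA was
measured, and the downstream analyses that make a stratification
clinically interpretable: survival and treatment-benefit comparisons,
concordance with alternative subtype systems, responder-stratification
gene set enrichment, and drug-sensitivity screening against subtype
probability.

The package is written for computational biologists analyzing bulk
expression cohorts (gastric cancer is the motivating disease), and for
anyone who needs a tested, reproducible implementation of the
compound covariate classification chain.

## The method in brief

1. **Discovery** — hierarchical clustering (correlation distance
   `1 − r`, average linkage) of samples over the most variable lncRNAs,
   cut at K subtypes.
2. **Signatures** — per subtype, one-vs-rest pooled-variance t-tests
   over all mRNAs; genes with `p < 0.001` and positive log2 ratio are
   ranked by log ratio and the top 200 kept.
3. **Classification** — per subtype, a compound score
   `s = Σ_g t_g · x_g` over z-scored signature genes, modeled as two
   Gaussians (class means, pooled SD σ); the Bayesian probability score
   is `P(in | s) = π φ(s; μ_in, σ) / [π φ(s; μ_in, σ) + (1−π) φ(s; μ_out, σ)]`,
   and samples are assigned by argmax over the K raw one-vs-rest
   posteriors. Validation is leave-one-out AUROC with full re-derivation
   of signatures and models inside the loop.
4. **Downstream** — Kaplan–Meier / log-rank prognosis (global +
   BH-adjusted pairwise), within-subtype treatment benefit,
   cross-tabulation against other classifications, pre-ranked GSEA, and
   mid-rank Spearman screening of drug AUC against subtype probability
   with a two-dataset concordance rule.

A synthetic-cohort generator (`cohort_config()`,
`generate_training_cohort()`, `apply_batch_shift()`,
`generate_survival()`, `generate_drug_panel()`) reproduces the data
structures these analyses assume, so the whole chain runs and is tested
without any external download. See the methods vignette
(`vignettes/lnc-subtyping-methods.Rmd`) for models, assumptions and
design decisions.

## Worked example

```r
library(lncsubtype)

cohort <- generate_training_cohort(cohort_config(seed = 11L))
centered <- median_center_genes(cohort$lnc)
clusters <- hierarchical_cluster(centered,
                                 select_variable_genes(centered, 1000),
                                 k = 6)
table(clusters$labels)
#>  1  2  3  4  5  6
#> 69 54 50 47 44 36

cv <- loocv_auc(cohort$mrna, clusters$labels)
round(cv$auc, 3)
#> subtype_1 subtype_2 subtype_3 subtype_4 subtype_5 subtype_6
#>         1         1         1         1         1         1

evaluate_k(centered, select_variable_genes(centered, 1000), 2:8)
#>   k mean_silhouette
#> 1 2       0.1803757
#> ...
#> 5 6       0.4272875   # maximum at the planted K
#> 6 7       0.3384823
```

The cluster sizes are the six planted subtypes recovered exactly
(adjusted Rand index 1 against the generator's labels); the
leave-one-out AUROC of 1.0 per subtype says each subtype's Bayesian
probability score perfectly ranks its members under cross-validation at
the default effect-to-noise ratio; and the silhouette profile peaks at
the generating K = 6.

The full analysis narrative lives in `analysis/01_simulate.R` …
`analysis/06_associations.R` — thin drivers that run each stage on a
simulated study and write tables under `results/`.

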