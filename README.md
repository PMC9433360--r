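# pam50x

Cross-species PAM50 molecular subtyping of mammary gland tumors.

Canine mammary gland tumors (CMGTs) arise spontaneously in an intact immune
environment and are a leading comparative model for human breast cancer.
Comparing the two species on equal footing requires classifying tumors from
both cohorts with one method on one scale. `pam50x` implements that
pipeline for R users working with bulk RNA-seq cohorts: it merges a canine
and a human expression cohort after per-cohort standardization, calls
estrogen-receptor (ER) status from the bimodal ESR1 distribution, corrects
the ER composition bias by gene centering, assigns each tumor the intrinsic
subtype (basal-like, HER2-enriched, luminal A, luminal B) of its
best-correlated reference centroid, and characterizes the resulting subtype
groups by signature scores, single-sample gene-set enrichment, tumor
mutation burden and copy-number aberration.

## The method

For gene *g* and sample *j* in cohort *c*, expression is standardized
within cohort, *z<sub>gj</sub>* = (*x<sub>gj</sub>* − mean<sub>c</sub>(*x<sub>g</sub>*)) / sd<sub>c</sub>(*x<sub>g</sub>*),
and the cohorts are merged over their common genes. ER status is called by
thresholding ESR1 at the minimum of its kernel density estimate between the
two modes (a tumor is ER⁺ iff ESR1 > cutoff). Each gene is then centered on
the unweighted average of its ER⁺ and ER⁻ stratum means, so the merged
cohort behaves as if it were 50/50 ER⁺ — the balance the reference
centroids assume. Classification is nearest-centroid: the Pearson
correlation *r<sub>jk</sub>* between the centered profile of tumor *j* and
centroid *k* is computed over the genes shared by data and centroids
(centroid genes absent from the data are dropped — on real cross-species
data 44 of the 50 panel genes), and the subtype is argmax<sub>k</sub>
*r<sub>jk</sub>*, with the margin to the runner-up reported.

Downstream: proliferation/immune scores (mean of standardized member-gene
expression), a rank-weighted single-sample enrichment statistic,
non-synonymous mutation filtering with FLAGS exclusion, segment-level
amplification/deletion calls at segment mean ±0.2, a per-tumor aberration
index (aberrant fraction of the covered genome), and the association tests
(Fisher exact r×c, Kruskal–Wallis, Mann–Whitney U, Pearson, Cohen's kappa).

A synthetic two-cohort generator (`simulate_cohorts()`) with known
subtype/ER/mutation/copy-number ground truth makes every stage testable
without downloading the original cohorts.

## Worked example

```r
library(pam50x)

sim <- simulate_cohorts(sim_config(n_samples_per_cohort = 60, seed = 42))
merged <- intersect_and_merge(zscore_by_gene(sim$expr_a),
                              zscore_by_gene(sim$expr_b))
fit <- pam50(merged, sim$centroids)
fit
#> Nearest-centroid intrinsic subtype fit
#>   120 samples classified over 44 panel genes (0 excluded)
#>   ER cutoff on ESR1: -0.5268; ER+ fraction 70.8%
#>          subtype
#> cohort    Basal-like HER2-enriched Luminal A Luminal B
#>   cohort1         17             8        29         6
#>   cohort2         20             3        35         2
```

The printed table is the subtype distribution per cohort; the ER cutoff is
the estimated ESR1 density minimum on the merged z-score scale (here
−0.53), and 44 panel genes were used because the second cohort lacks six
of the 50. `summary(fit)` adds the per-subtype median (IQR) of the
correlation to the assigned centroid, e.g. luminal A
`0.88 (0.86-0.90)` in cohort 1 — the classical way these cohorts are
described. Against the generator's truth labels this fit recovers 100% of
subtypes:

```r
truth <- sim$truth$true_subtype[match(fit$calls$sample_id, sim$truth$sample_id)]
mean(fit$calls$subtype == truth)
#> [1] 1
```

Association testing against clinical annotation uses the bundled
cross-tabulations of the published 157-tumor canine cohort:

```r
tabs <- cmgt_clinical_tables()
fisher_exact_rc(tabs$lymph_node)
#> Fisher exact (r x c): p = 0.000271 (exact network enumeration)
```

meaning lymph-node invasion is very unevenly distributed across the four
subtypes (it concentrates in basal-like tumors).

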