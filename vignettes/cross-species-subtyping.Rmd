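---
title: "Cross-species intrinsic subtyping: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species intrinsic subtyping: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pam50x)
```

## The problem and the model

Intrinsic molecular subtypes (basal-like, HER2-enriched, luminal A,
luminal B) organize mammary tumor biology far better than histology alone,
and a canine cohort can only be compared with a human cohort if both are
classified by the same rule on the same scale. `pam50x` implements that
rule as a nearest-centroid classifier over a 50-gene panel.

The pipeline makes three modelling assumptions worth stating explicitly:

1. **Per-cohort standardization removes the species/platform effect.**
   Each gene is z-scored within its cohort (sample s.d., $n-1$) before
   merging. This removes cohort-level location and scale per gene and
   nothing else; no further batch correction is applied. It assumes the
   *rank structure across samples within a cohort* is comparable between
   species. On synthetic equal-structure cohorts the merged data show no
   cohort separation on the leading principal components (tested by a
   permutation check).
2. **ER status is readable from ESR1 alone.** ESR1 expression is strongly
   bimodal in mammary cohorts, so a tumor is called ER-positive iff its
   merged-scale ESR1 value is strictly above the minimum of the kernel
   density between the two modes. The strict inequality is a deterministic
   boundary convention.
3. **The reference centroids assume a roughly ER-balanced cohort.** Test
   cohorts are ~75% ER-positive; uncorrected, this composition shifts
   every gene's center toward the ER-positive profile and biases the
   correlations. The correction is gene centering informed by the ER
   strata (next section).

Classification itself: for tumor $j$ and centroid $k$, the Pearson
correlation $r_{jk}$ is computed over the genes shared by the centered
matrix and the centroid table (centroid genes missing from the data are
dropped — the reduced 44-gene panel on real cross-species data), and the
assigned subtype is $\arg\max_k r_{jk}$. Ties are broken by the canonical
subtype order and flagged; the margin (best minus second-best correlation)
is reported because it carries real information — diffuse subtypes sit
near several centroids at once.

## ER centering: a genuinely open design point

"Gene centering separately for ER$^+$ and ER$^-$ tumors" admits two
readings, and the distinction matters:

* **Within-stratum centering** (`er_stratified_center()`, and
  `pam50(center = "stratum_mean"/"stratum_median")`): each gene's mean (or
  median) is set to zero inside each stratum. This is the literal reading
  and is kept, exported and tested. Its weakness is geometric: strata have
  skewed subtype composition (the ER-negative stratum is dominated by
  basal-like tumors), so the subtracted stratum mean is itself a
  basal-like profile. Because the basal-like and luminal A centroids are
  strongly anticorrelated, removing it pushes *every* ER-negative residual
  toward luminal A — enough to flip weakly-separated ER-negative
  HER2-enriched tumors even in the zero-noise limit.
* **ER-balanced centering** (`er_balanced_center()`, the `pam50()`
  default): each gene is centered on the unweighted average of its two
  stratum means — one common offset per gene. This performs the same
  composition correction (the centered cohort behaves as if it were 50/50
  ER-positive) but, being a single shift, preserves all between-sample
  geometry. Under the balanced default the classifier attains exact
  recovery in the zero-noise limit and full recovery at the simulated
  study noise.

We default to the balanced variant for that reason and document the choice
here rather than silently picking one; the stratified variants remain one
argument away. Median-based centering of both kinds is provided because
parts of the centering literature prefer medians; on the synthetic
geometry the mean/median distinction is minor, while the
within-stratum/balanced distinction is not.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `noise_sd` | 0.5 | within-subtype expression s.d. around the centroid (z-scale units) |
| `esr1_modes`, `mode_sd` | −2 / +2, 0.5 | ESR1 mode locations and spread; 4 s.d. separation keeps the marginal clearly bimodal |
| `er_by_subtype` | 0.35, 0.30, 0.95, 0.90 | P(ER$^+$ | subtype); gives ~75% ER$^+$ overall with partially ER$^+$ basal-like tumors, as seen in canine cohorts |
| `subtype_proportions` | 0.268, 0.089, 0.586, 0.057 | the observed canine cohort distribution |
| `amp_cut`, `del_cut` | +0.2 / −0.2 | segment-mean thresholds for amplification/deletion calls (log-ratio scale, strict inequalities) |
| `alpha` (ssGSEA) | 0.75 | rank-weight exponent of the enrichment running sum |
| `threshold_sd` (outlier screen) | 6 | MAD-scaled distance from the PC1/PC2 median before a sample is flagged |

The outlier screen deliberately reports rather than removes: dropping a
sample is a caller decision (`pca_outlier_screen()` returns the flagged
IDs with their scores).

## What the synthetic generator emulates — and what it does not

`simulate_cohorts()` draws two cohorts around block-structured centroids
(`synthetic_centroids()`): a proliferation block high in basal-like and
luminal B, a luminal/hormone-receptor block high in the luminal subtypes,
a small ERBB2 block high in HER2-enriched, and a basal block. HER2-enriched
and luminal B are configured deliberately less distinct — intermediate
block values — because that is how they present in real cohorts: their
assignment margins are smaller and their correlation summaries flatter,
and tests assert exactly that qualitative pattern. ESR1 is overridden with
a draw from the mode matching the sample's true ER status, producing the
bimodal marginal the cutoff estimator needs. Cohort 2 lacks six panel
genes, reproducing the reduced-panel situation. Clinical labels are drawn
from the subtype-conditional frequencies of the published 157-tumor canine
cross-tabulations; mutations are Bernoulli per (sample, gene) with
PIK3CA-luminal and TP53-basal enrichment; segments tile a 5×100 Mb toy
genome with subtype-dependent aberrant fractions (basal 0.40 > luminal B
0.30 > HER2 0.10 ≈ luminal A 0.05).

What it does **not** emulate: read-level noise, gene–gene correlation
beyond the block structure, chromosomal synteny or species-specific
transcript structure, copy-number/expression coupling, and tumor purity.
Passing recovery tests on this generator therefore demonstrates that the
*pipeline* is correct and well-calibrated under its stated model — not
that the biological classifier would reach the same accuracy on real data,
where subtype boundaries are fuzzier than any Gaussian-around-centroid
model.

## Numerical choices

* **Cutoff estimator**: Gaussian KDE with Silverman's rule-of-thumb
  bandwidth on a 512-point grid spanning the data range ±3 bandwidths; the
  cutoff is the grid minimum strictly between the two highest local
  maxima; fewer than two maxima is an error, not a silent fallback.
* **Z-scores** use the $n-1$ sample s.d.; zero-variance genes become
  all-zero rows and are flagged rather than dropped.
* **Missing values** are excluded pairwise from correlations (the least
  destructive convention); duplicate gene rows and many-to-one ortholog
  collisions are collapsed by the mean (symmetric, scale-preserving), with
  a warning.
* **Gene intersection** is ordered lexicographically so merges are
  deterministic and symmetric in gene content.
* **Fisher r×c**: exact network enumeration is attempted first; tables too
  large to enumerate fall back to Monte-Carlo with a fixed seed, the
  p-value floored at $1/(B+1)$ and reported with its standard error.
  Mann–Whitney U uses exact enumeration for small untied samples,
  otherwise the tie-corrected normal approximation. All tests are
  two-sided.
* **ssGSEA ties** in expression are broken lexicographically by gene
  symbol, making scores deterministic; a set covering every gene has no
  out-set and scores 0 by convention.
* **Gene-level copy number** takes the longest-overlap segment (with an
  overlap-weighted mean as an option); SEG coordinates are 1-based
  inclusive throughout.
* **TMB** counts retained mutation rows per tumor, while recurrence counts
  *distinct tumors* per gene — two different questions, kept deliberately
  distinct.

## Problem sizes used in the checks

The bundled checks run the generator at 400 samples per cohort and 500
genes for the study-condition recovery (with a 150-per-cohort zero-noise
companion), 1,000 random toy segments for the copy-number oracle
comparison, and $10^6$ Monte-Carlo replicates for the 5×4 histopathology
table — sizes chosen so each estimate is comfortably stable at the
tolerances asserted.

## Known limitations

* The classifier presumes the four-subtype world; a normal-like column in
  a centroid table is rejected rather than handled.
* The ER cutoff requires genuine bimodality; cohorts where ESR1 is
  unimodal (e.g. heavily ER-positive-enriched selections) are an error by
  design.
* Aberration indices depend on the covered genome of each sample's
  segments; cohorts with very different coverage are not directly
  comparable.
* The package consumes VEP-annotated variant tables and segmented
  copy-number input; it does not align, call variants, or segment.
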