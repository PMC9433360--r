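Package: pam50x
Title: Cross-Species PAM50 Molecular Subtyping of Mammary Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nearest-centroid PAM50 intrinsic subtyping of mammary gland
    tumors across species (canine and human cohorts), with per-cohort
    gene-wise standardization and merging, an ESR1 density-minimum estrogen
    receptor call, ER-stratified gene centering, reduced-panel centroid
    correlation, and subtype-stratified characterization of mutation burden
    and copy-number aberration. Includes a synthetic two-cohort generator
    with known subtype, ER, mutation and copy-number ground truth, readers
    and writers for expression, clinical, SEG, variant and GMT tables,
    signature and single-sample gene-set enrichment scores, and the
    association statistics (Fisher exact r x c, Kruskal-Wallis,
    Mann-Whitney U, Pearson, Cohen's kappa) used to relate subtypes to
    clinical and genomic features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
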