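# Cross-cohort harmonization: gene-wise standardization within each cohort,
# gene-set intersection and merging, and the PCA-based outlier screen and
# cross-cohort projection. Standardizing per cohort before merging removes
# cohort-level location/scale differences without any further batch
# correction.

#' Log2-transform a linear-scale expression matrix
#'
#' Applies `log2(x + pseudocount)` and updates the recorded scale. Refuses
#' to transform a matrix already on log or z-score scale, and refuses
#' negative input on linear scale.
#'
#' @param m Gene x sample matrix on linear (e.g. FPKM) scale.
#' @param pseudocount Offset added before the log (default 1).
#' @return Transformed matrix with scale `"log2"`.
#' @export
log_transform <- function(m, pseudocount = 1) {
  sc <- expr_scale(m)
  if (sc != "linear") .stop("already log scale (scale = '", sc, "')")
  .assert(all(m >= 0 | is.na(m)), "negative values on linear scale")
  carry_meta(log2(m + pseudocount), m, scale = "log2")
}

#' Gene-wise z-score standardization
#'
#' Transforms each gene row to `(x - mean) / sd` using the sample standard
#' deviation (n - 1 denominator), computed over non-missing values.
#' Zero-variance rows become all zero and are flagged in the result's
#' `"zero_variance"` attribute.
#'
#' @param m Gene x sample matrix with at least two samples.
#' @return Standardized matrix with scale `"zscore"`.
#' @export
zscore_by_gene <- function(m) {
  .assert(ncol(m) >= 2, "z-scoring needs at least two samples")
  mu <- rowMeans(m, na.rm = TRUE)
  sd <- apply(m, 1, stats::sd, na.rm = TRUE)
  zero <- !is.na(sd) & sd == 0
  sd[zero | sd == 0 | is.na(sd)] <- 1
  z <- (m - mu) / sd
  z[zero, ] <- 0
  carry_meta(z, m, scale = "zscore",
             extra = list(zero_variance = rownames(m)[zero]))
}

#' Intersect gene sets and merge two standardized cohorts
#'
#' Restricts both matrices to their common genes (ordered
#' lexicographically, so the merge is symmetric in gene content) and
#' concatenates the samples, tagging each with its cohort. Both inputs must
#' already be on z-score scale: merging is defined on per-cohort
#' standardized data so that neither cohort dominates the merged scale.
#'
#' @param a,b Gene x sample matrices with scale `"zscore"` (see
#'   [zscore_by_gene()]).
#' @return Merged matrix with attributes `cohorts` (per-sample tag) and
#'   `n_intersection` (size of the common gene set).
#' @export
intersect_and_merge <- function(a, b) {
  .assert(expr_scale(a) == "zscore" && expr_scale(b) == "zscore",
          "both matrices must be z-scored before merging")
  genes <- sort(intersect(rownames(a), rownames(b)))
  .assert(length(genes) > 0, "empty gene intersection")
  .assert(!any(colnames(a) %in% colnames(b)),
          "duplicate sample IDs across cohorts")
  merged <- cbind(a[genes, , drop = FALSE], b[genes, , drop = FALSE])
  tag_a <- expr_cohort(a); tag_b <- expr_cohort(b)
  if (is.na(tag_a)) tag_a <- "cohort_a"
  if (is.na(tag_b)) tag_b <- "cohort_b"
  cohorts <- stats::setNames(
    rep(c(tag_a, tag_b), c(ncol(a), ncol(b))), colnames(merged))
  attr(merged, "cohorts") <- cohorts
  attr(merged, "scale") <- "zscore"
  attr(merged, "n_intersection") <- length(genes)
  merged
}

#' PCA-based sample outlier screen
#'
#' Flags samples whose PC1 or PC2 score lies more than `threshold_sd`
#' robust standard deviations (MAD-scaled) from the component median.
#' Flagged samples are reported; removing them is the caller's choice.
#' The default threshold of 6 is conservative: on a homogeneous Gaussian
#' cloud it flags essentially nothing.
#'
#' @param m Gene x sample matrix (>= 3 samples).
#' @param threshold_sd Robust-SD threshold (default 6).
#' @return Character vector of flagged sample IDs (possibly empty), with
#'   the PC1/PC2 score table as attribute `"scores"`.
#' @export
pca_outlier_screen <- function(m, threshold_sd = 6) {
  .assert(ncol(m) >= 3, "outlier screen needs at least three samples")
  p <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(p$x))
  scores <- p$x[, seq_len(k), drop = FALSE]
  flagged <- rep(FALSE, nrow(scores))
  for (j in seq_len(k)) {
    s <- scores[, j]
    spread <- stats::mad(s)
    if (spread == 0) next  # no usable spread on this component
    flagged <- flagged | abs(s - stats::median(s)) / spread > threshold_sd
  }
  out <- rownames(scores)[flagged]
  attr(out, "scores") <- scores
  out
}

#' Fit a PCA on a reference cohort and project a query cohort
#'
#' Components are fitted on the reference samples only; query samples are
#' centered with the reference gene means and projected onto the reference
#' loadings, so both clouds live in one coordinate system. The per-gene
#' contribution to each component (squared loading, summing to 1) is
#' reported to rank genes driving the separation.
#'
#' @param reference Gene x sample matrix the components are fitted on.
#' @param query Gene x sample matrix to overlay; its genes must be a subset
#'   of the reference genes (both are restricted to the query genes).
#' @param n_components Number of components (<= min dimension).
#' @return List: `scores_reference`, `scores_query` (sample x component),
#'   `loadings` (gene x component), `contributions` (squared loadings,
#'   columns sum to 1), `var_explained` (fraction per component).
#' @export
pca_project <- function(reference, query, n_components = 2) {
  .assert(all(rownames(query) %in% rownames(reference)),
          "query genes must be a subset of reference genes")
  genes <- rownames(query)
  ref <- t(reference[genes, , drop = FALSE])
  .assert(n_components <= min(dim(ref)),
          "n_components exceeds the data dimension")
  p <- stats::prcomp(ref, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  rot <- p$rotation[, k, drop = FALSE]
  qs <- scale(t(query[genes, , drop = FALSE]), center = p$center,
              scale = FALSE) %*% rot
  list(
    scores_reference = p$x[, k, drop = FALSE],
    scores_query = qs,
    loadings = rot,
    contributions = sweep(rot^2, 2, colSums(rot^2), "/"),
    var_explained = (p$sdev^2 / sum(p$sdev^2))[k])
}
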