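# ER-status calling from bimodal ESR1 expression, ER-stratified gene
# centering, and nearest-centroid subtype assignment. The classifier
# correlates each tumor's centered panel profile with the four subtype
# centroids (Pearson) and assigns the best-correlated subtype; genes absent
# from the expression data are dropped from the centroids, which is how the
# 44-of-50-gene reduced panel arises on real cross-species data.

#' Estimate a bimodality cutoff from a kernel density
#'
#' Fits a Gaussian kernel density (Silverman's rule-of-thumb bandwidth,
#' 512-point grid spanning the data range plus three bandwidths) and places
#' the cutoff at the grid point of minimum density strictly between the two
#' highest local maxima. A density with fewer than two local maxima is an
#' error: there is no bimodal structure to threshold.
#'
#' @param values Numeric vector (>= 20 finite values), typically merged
#'   ESR1 z-scores.
#' @return An object of class `er_cutoff`: list with `cutoff`, `modes`
#'   (locations of the two highest maxima), `bandwidth` and the `density`
#'   object.
#' @export
#' @examples
#' set.seed(1)
#' x <- c(rnorm(250, -2, 0.3), rnorm(250, 2, 0.3))
#' estimate_bimodal_cutoff(x)$cutoff
estimate_bimodal_cutoff <- function(values) {
  x <- values[is.finite(values)]
  .assert(length(x) >= 20, "need at least 20 finite values")
  d <- stats::density(x, bw = "nrd0", n = 512, cut = 3)
  y <- d$y
  n <- length(y)
  # interior local maxima (plateaus count once, at their left edge)
  is_max <- which(diff(sign(diff(y))) < 0) + 1L
  if (y[1] > y[2]) is_max <- c(1L, is_max)
  if (y[n] > y[n - 1]) is_max <- c(is_max, n)
  if (length(is_max) < 2) .stop("no bimodal structure in the density")
  top2 <- sort(is_max[order(y[is_max], decreasing = TRUE)][1:2])
  .assert(top2[2] - top2[1] > 1, "modes are adjacent; no interior minimum")
  interior <- (top2[1] + 1):(top2[2] - 1)
  cut_idx <- interior[which.min(y[interior])]
  structure(list(
    cutoff = d$x[cut_idx],
    modes = d$x[top2],
    bandwidth = d$bw,
    density = d), class = "er_cutoff")
}

#' @export
print.er_cutoff <- function(x, ...) {
  cat(sprintf("ER cutoff %.4f (modes at %.3f and %.3f, bandwidth %.3f)\n",
              x$cutoff, x$modes[1], x$modes[2], x$bandwidth))
  invisible(x)
}

#' Call ER status from ESR1 expression
#'
#' A tumor is ER-positive iff its ESR1 value is strictly greater than the
#' cutoff; a value exactly at the cutoff is negative.
#'
#' @param m Merged gene x sample matrix containing `esr1_gene`.
#' @param cutoff An `er_cutoff` object or a bare numeric cutoff.
#' @param esr1_gene Row to threshold (default `"ESR1"`).
#' @return Named character vector (`"pos"`/`"neg"`) per sample, with
#'   per-cohort positive counts in attribute `"counts"` when the matrix
#'   carries cohort tags.
#' @export
call_er_status <- function(m, cutoff, esr1_gene = "ESR1") {
  .assert(esr1_gene %in% rownames(m), esr1_gene, " not present in the matrix")
  cut <- if (inherits(cutoff, "er_cutoff")) cutoff$cutoff else cutoff
  er <- stats::setNames(ifelse(m[esr1_gene, ] > cut, "pos", "neg"),
                        colnames(m))
  ch <- attr(m, "cohorts")
  if (!is.null(ch)) attr(er, "counts") <- table(cohort = ch, er = er)
  er
}

#' ER-stratified gene centering
#'
#' Centers each gene separately within the ER-positive and ER-negative
#' strata (pooled across cohorts), so that the classifier is not biased by
#' the cohorts' ER-positive fraction differing from that of the cohort the
#' centroids were trained on. With `method = "median"` the stratum median
#' is subtracted instead of the mean.
#'
#' @param m Merged gene x sample matrix.
#' @param er Per-sample ER labels (`"pos"`/`"neg"`), as from
#'   [call_er_status()]; both strata need >= 2 samples.
#' @param method `"mean"` (default) or `"median"`.
#' @return Centered matrix with unchanged metadata.
#' @export
er_stratified_center <- function(m, er, method = c("mean", "median")) {
  method <- match.arg(method)
  er <- er[colnames(m)]
  .assert(!any(is.na(er)), "every sample needs an ER label")
  .assert(all(table(factor(er, c("pos", "neg"))) >= 2),
          "each ER stratum needs at least two samples")
  fun <- if (method == "mean") rowMeans else function(x) apply(x, 1, stats::median)
  out <- m
  for (lev in c("pos", "neg")) {
    idx <- which(er == lev)
    out[, idx] <- m[, idx, drop = FALSE] - fun(m[, idx, drop = FALSE])
  }
  out
}

#' ER-balanced gene centering
#'
#' Centers every gene on the unweighted average of its ER-positive and
#' ER-negative stratum means -- one common per-gene offset for all samples.
#' Like [er_stratified_center()] this neutralizes the cohort's ER
#' composition (the centered data behave as if the cohort were 50/50
#' ER-positive, matching the balance the reference centroids assume), but
#' because the offset is shared it preserves all between-sample geometry;
#' within-stratum centering can distort nearest-centroid assignment when
#' one stratum is dominated by a single subtype.
#'
#' @inheritParams er_stratified_center
#' @return Centered matrix with unchanged metadata.
#' @export
er_balanced_center <- function(m, er, method = c("mean", "median")) {
  method <- match.arg(method)
  er <- er[colnames(m)]
  .assert(!any(is.na(er)), "every sample needs an ER label")
  .assert(all(table(factor(er, c("pos", "neg"))) >= 2),
          "each ER stratum needs at least two samples")
  fun <- if (method == "mean") rowMeans else function(x) apply(x, 1, stats::median)
  ref <- (fun(m[, er == "pos", drop = FALSE]) +
            fun(m[, er == "neg", drop = FALSE])) / 2
  m - ref
}

#' Correlate centered tumor profiles with subtype centroids
#'
#' Pearson correlation between each sample's centered expression and each
#' centroid, over the genes shared by matrix and centroids (centroid genes
#' missing from the matrix are dropped; missing values are excluded
#' pairwise). A sample with zero variance over the shared genes gets `NA`
#' correlations and is flagged.
#'
#' @param centered Gene x sample matrix (ER-stratified centered).
#' @param centroids Gene x 4 centroid matrix.
#' @return Sample x 4 correlation matrix (columns in canonical subtype
#'   order) with attributes `"genes_used"` and `"flagged"` (zero-variance
#'   samples).
#' @export
correlate_to_centroids <- function(centered, centroids) {
  genes <- intersect(rownames(centroids), rownames(centered))
  .assert(length(genes) >= 3, "need at least 3 genes shared with the centroids")
  x <- centered[genes, , drop = FALSE]
  ct <- centroids[genes, , drop = FALSE]
  r <- suppressWarnings(stats::cor(x, ct, use = "pairwise.complete.obs"))
  sdx <- apply(x, 2, stats::sd, na.rm = TRUE)
  flagged <- colnames(x)[!is.na(sdx) & sdx == 0]
  r[colnames(x) %in% flagged, ] <- NA_real_
  attr(r, "genes_used") <- genes
  attr(r, "flagged") <- flagged
  r
}

#' Assign the best-correlated subtype
#'
#' Argmax assignment over the four centroid correlations. Ties on the
#' maximum are broken by canonical subtype order and flagged; samples with
#' any non-finite correlation are excluded with a logged reason.
#'
#' @param correlations Sample x 4 correlation matrix from
#'   [correlate_to_centroids()].
#' @return Data frame `sample_id`, `subtype`, `margin` (best minus
#'   second-best correlation), `tie_flag`; excluded samples are listed in
#'   attribute `"excluded"`.
#' @export
assign_subtype <- function(correlations) {
  st <- pam50_subtypes()
  .assert(ncol(correlations) == 4 && all(colnames(correlations) %in% st),
          "correlations must have the four canonical subtype columns")
  correlations <- correlations[, st, drop = FALSE]
  ok <- apply(is.finite(correlations), 1, all)
  excluded <- rownames(correlations)[!ok]
  if (length(excluded) > 0) {
    message(length(excluded),
            " sample(s) excluded (non-finite centroid correlation): ",
            paste(utils::head(excluded, 5), collapse = ", "))
  }
  r <- correlations[ok, , drop = FALSE]
  best <- apply(r, 1, which.max)  # first max = canonical-order tie-break
  sorted <- t(apply(r, 1, sort, decreasing = TRUE))
  tie <- apply(r, 1, function(v) sum(v == max(v)) > 1)
  out <- data.frame(
    sample_id = rownames(r),
    subtype = st[best],
    margin = sorted[, 1] - sorted[, 2],
    tie_flag = tie,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "excluded") <- excluded
  out
}

#' Compare classifier panels by subtype-correlation agreement
#'
#' Runs the centroid correlation twice, restricting the gene panel to
#' `panel_a` and then `panel_b`, and reports for each subtype the Pearson
#' correlation across samples between the two sets of centroid
#' correlations. Values near 1 mean the reduced panel preserves the
#' classifier geometry.
#'
#' @param centered Centered gene x sample matrix.
#' @param centroids Gene x 4 centroid matrix.
#' @param panel_a,panel_b Gene panels (subsets of the centroid genes).
#' @return Named length-4 numeric vector of per-subtype correlations.
#' @export
panel_reduction_check <- function(centered, centroids, panel_a, panel_b) {
  .assert(all(panel_a %in% rownames(centroids)) &&
            all(panel_b %in% rownames(centroids)),
          "panels must be subsets of the centroid genes")
  ra <- correlate_to_centroids(centered[intersect(rownames(centered), panel_a), ,
                                        drop = FALSE], centroids)
  rb <- correlate_to_centroids(centered[intersect(rownames(centered), panel_b), ,
                                        drop = FALSE], centroids)
  vapply(pam50_subtypes(), function(s) {
    stats::cor(ra[, s], rb[, s], use = "complete.obs")
  }, numeric(1))
}

#' Cohen's kappa concordance between two call sets
#'
#' Unweighted Cohen's kappa on the k x k agreement table of two categorical
#' labelings of the same samples (matched by name when both are named).
#'
#' @param calls_a,calls_b Character or factor vectors of class labels.
#' @return Kappa coefficient (scalar).
#' @export
concordance_kappa <- function(calls_a, calls_b) {
  if (!is.null(names(calls_a)) && !is.null(names(calls_b))) {
    common <- intersect(names(calls_a), names(calls_b))
    .assert(length(common) > 0, "no samples in common")
    calls_a <- calls_a[common]
    calls_b <- calls_b[common]
  }
  .assert(length(calls_a) == length(calls_b) && length(calls_a) > 0,
          "call sets must have the same (positive) length")
  levs <- sort(union(unique(as.character(calls_a)),
                     unique(as.character(calls_b))))
  tab <- table(factor(calls_a, levs), factor(calls_b, levs))
  kappa_from_table(tab)
}

# (p_o - p_e) / (1 - p_e) on a square agreement table.
kappa_from_table <- function(tab) {
  n <- sum(tab)
  .assert(n > 0, "empty agreement table")
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  .assert(pe < 1, "degenerate table: expected agreement is 1")
  (po - pe) / (1 - pe)
}
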