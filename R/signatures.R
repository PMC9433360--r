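# Gene-signature scores (proliferation, immune) and a single-sample
# gene-set enrichment statistic. Signature scores are means of standardized
# member-gene expression; the enrichment score is the rank-based
# weighted-ECDF running-sum statistic, computed per sample.

#' Proliferation signature genes
#'
#' The 10 proliferation-associated genes whose mean standardized expression
#' defines the proliferation score. (The original 11-gene signature also
#' contains BIRC5, which is absent from the canine expression data; missing
#' members are skipped and counted by [signature_score()].)
#'
#' @return Character vector of 10 gene symbols.
#' @export
proliferation_genes <- function() {
  c("CCNB1", "CDC20", "NUF2", "CEP55", "NDC80",
    "MKI67", "PTTG1", "RRM2", "TYMS", "UBE2C")
}

#' Mean-of-standardized-members signature score
#'
#' Standardizes each member gene across all samples of the matrix (z-score,
#' n - 1 denominator; standardization is computed on the full merged cohort
#' so the two species are scored on one scale) and averages the member
#' z-values per sample. Members absent from the matrix are skipped and
#' counted; zero-variance members contribute 0.
#'
#' @param m Gene x sample matrix.
#' @param genes Character vector of member symbols, or a gene-set list with
#'   a `members` element (as from [read_gmt()]).
#' @param name Signature name recorded in the output.
#' @return Data frame `sample_id`, `signature`, `score`, with attributes
#'   `"n_used"` and `"n_total"`.
#' @export
#' @examples
#' sim <- simulate_cohorts(sim_config(n_samples_per_cohort = 20, seed = 3))
#' ps <- signature_score(sim$expr_a, proliferation_genes(), "proliferation")
#' head(ps)
signature_score <- function(m, genes, name = "signature") {
  if (is.list(genes)) genes <- genes$members
  present <- intersect(genes, rownames(m))
  .assert(length(present) > 0, "no signature member genes present")
  z <- zscore_by_gene(m[present, , drop = FALSE])
  out <- data.frame(sample_id = colnames(m),
                    signature = name,
                    score = colMeans(z),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_used") <- length(present)
  attr(out, "n_total") <- length(genes)
  out
}

# Enrichment running sum for one sample: genes ordered by decreasing
# expression (ties broken by symbol), in-set steps weighted by rank^alpha,
# out-set steps uniform; ES is the sum of the ECDF differences.
ssgsea_sample_es <- function(x, symbols, members, alpha) {
  n <- length(x)
  ord <- order(-x, symbols)
  in_set <- symbols[ord] %in% members
  n_out <- n - sum(in_set)
  if (n_out == 0) return(0)  # degenerate: set covers the whole matrix
  rnk <- seq(n, 1)  # rank weight: highest expression gets rank n
  w <- ifelse(in_set, rnk^alpha, 0)
  cdf_in <- cumsum(w) / sum(w)
  cdf_out <- cumsum(!in_set) / n_out
  sum(cdf_in - cdf_out)
}

#' Single-sample gene-set enrichment scores
#'
#' For each sample, genes are ranked by expression (ties broken
#' lexicographically by symbol, so results are deterministic) and the
#' enrichment score is the sum over the ranked list of the difference
#' between the rank-weighted in-set cumulative distribution
#' (weights rank^`alpha`) and the uniform out-set cumulative distribution.
#' Because it depends on ranks only, the score is invariant to any
#' increasing transform of a sample's expression values.
#'
#' @param m Gene x sample matrix.
#' @param genesets Named list of gene sets (each with a `members` element,
#'   as from [read_gmt()]) or a plain named list of symbol vectors.
#' @param alpha Rank-weight exponent (default 0.75).
#' @param normalize If `TRUE`, divide all scores by the range
#'   (max - min) of the raw scores across the whole result table.
#' @return Data frame `sample_id`, `gene_set`, `es`. Sets with fewer than
#'   two members present in the matrix are skipped with a warning; a set
#'   covering every gene has no out-set and scores 0 by convention.
#' @export
ssgsea <- function(m, genesets, alpha = 0.75, normalize = FALSE) {
  if (!is.null(genesets$members)) genesets <- list(set = genesets)
  members <- lapply(genesets, function(gs) if (is.list(gs)) gs$members else gs)
  symbols <- rownames(m)
  keep <- vapply(members, function(g) sum(g %in% symbols) >= 2, logical(1))
  if (any(!keep)) {
    warning("skipping gene set(s) with < 2 members present: ",
            paste(names(members)[!keep], collapse = ", "), call. = FALSE)
  }
  members <- members[keep]
  .assert(length(members) > 0, "no usable gene sets")
  res <- lapply(names(members), function(nm) {
    es <- apply(m, 2, ssgsea_sample_es, symbols = symbols,
                members = members[[nm]], alpha = alpha)
    data.frame(sample_id = colnames(m), gene_set = nm, es = unname(es),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  if (normalize) {
    rng <- diff(range(out$es))
    if (rng > 0) out$es <- out$es / rng
  }
  out
}

#' Compare signature or enrichment scores between groups
#'
#' Delegates to the package's rank tests: Mann-Whitney U for two groups,
#' Kruskal-Wallis for more.
#'
#' @param scores Numeric score vector.
#' @param groups Group label per score.
#' @param test `"auto"` (default: MWU for 2 groups, KW otherwise),
#'   `"mwu"` or `"kruskal"`.
#' @return A test-result list (see [mann_whitney_u()]) with an added
#'   `medians` element (per-group medians).
#' @export
score_group_contrast <- function(scores, groups,
                                 test = c("auto", "mwu", "kruskal")) {
  test <- match.arg(test)
  g <- split(scores, groups)
  g <- g[vapply(g, length, integer(1)) > 0]
  .assert(length(g) >= 2, "need at least two non-empty groups")
  .assert(all(vapply(g, length, integer(1)) >= 2),
          "each group needs at least two values")
  if (test == "auto") test <- if (length(g) == 2) "mwu" else "kruskal"
  res <- if (test == "mwu") {
    .assert(length(g) == 2, "Mann-Whitney U compares exactly two groups")
    mann_whitney_u(g[[1]], g[[2]])
  } else {
    kruskal_wallis(g)
  }
  res$medians <- vapply(g, stats::median, numeric(1))
  res
}
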