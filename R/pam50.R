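#' Nearest-centroid intrinsic subtyping of a merged cohort
#'
#' The central fitting function: given a merged, per-cohort standardized
#' expression matrix (see [intersect_and_merge()]) and a subtype centroid
#' matrix, it (1) estimates the ESR1 bimodality cutoff (unless supplied)
#' and calls ER status, (2) centers every gene within the ER-positive and
#' ER-negative strata, (3) correlates each tumor's centered profile with
#' the four centroids over the shared gene panel, and (4) assigns the
#' best-correlated subtype.
#'
#' @param merged Gene x sample matrix from [intersect_and_merge()] (or any
#'   z-scored matrix with per-sample cohort tags in attribute `cohorts`).
#' @param centroids Gene x 4 centroid matrix (default
#'   [synthetic_centroids()]; supply a reference centroid table via
#'   [read_centroids()] for real data).
#' @param er_gene Gene used for the ER call (default `"ESR1"`).
#' @param er_cutoff Optional precomputed [estimate_bimodal_cutoff()] result
#'   or bare numeric cutoff; estimated from `er_gene` when `NULL`.
#' @param center ER-composition correction: `"balanced"` (default,
#'   [er_balanced_center()] with stratum means), `"balanced_median"`, or
#'   within-stratum centering `"stratum_mean"` / `"stratum_median"`
#'   ([er_stratified_center()]).
#' @return Object of class `pam50_fit`: list with `calls` (data frame:
#'   `sample_id`, `cohort`, `er_status`, one correlation column per
#'   subtype, `subtype`, `margin`, `tie_flag`), `correlations` (sample x 4
#'   matrix), `er_cutoff`, `genes_used`, `centroids`, `excluded`.
#' @seealso [summary.pam50_fit()] for per-subtype correlation summaries,
#'   [predict.pam50_fit()] to classify further samples.
#' @export
#' @examples
#' sim <- simulate_cohorts(sim_config(n_samples_per_cohort = 60, seed = 2))
#' merged <- intersect_and_merge(zscore_by_gene(sim$expr_a),
#'                               zscore_by_gene(sim$expr_b))
#' fit <- pam50(merged, sim$centroids)
#' fit
#' mean(fit$calls$subtype ==
#'        sim$truth$true_subtype[match(fit$calls$sample_id,
#'                                     sim$truth$sample_id)])
pam50 <- function(merged, centroids = synthetic_centroids(),
                  er_gene = "ESR1", er_cutoff = NULL,
                  center = c("balanced", "balanced_median",
                             "stratum_mean", "stratum_median")) {
  center <- match.arg(center)
  cohorts <- attr(merged, "cohorts")
  if (is.null(cohorts)) {
    cohorts <- stats::setNames(rep(NA_character_, ncol(merged)),
                               colnames(merged))
  }
  if (is.null(er_cutoff)) {
    .assert(er_gene %in% rownames(merged),
            er_gene, " not present in the merged matrix")
    er_cutoff <- estimate_bimodal_cutoff(merged[er_gene, ])
  }
  er <- call_er_status(merged, er_cutoff, esr1_gene = er_gene)
  centered <- apply_er_centering(merged, er, center)
  correlations <- correlate_to_centroids(centered, centroids)
  assignment <- assign_subtype(correlations)
  idx <- match(assignment$sample_id, colnames(merged))
  calls <- data.frame(
    sample_id = assignment$sample_id,
    cohort = unname(cohorts[idx]),
    er_status = unname(er[idx]),
    correlations[assignment$sample_id, , drop = FALSE],
    subtype = assignment$subtype,
    margin = assignment$margin,
    tie_flag = assignment$tie_flag,
    stringsAsFactors = FALSE, row.names = NULL, check.names = FALSE)
  structure(list(
    calls = calls,
    correlations = correlations,
    er_cutoff = er_cutoff,
    genes_used = attr(correlations, "genes_used"),
    centroids = centroids,
    center = center,
    er_gene = er_gene,
    excluded = attr(assignment, "excluded")), class = "pam50_fit")
}

apply_er_centering <- function(m, er, center) {
  switch(center,
         balanced = er_balanced_center(m, er, "mean"),
         balanced_median = er_balanced_center(m, er, "median"),
         stratum_mean = er_stratified_center(m, er, "mean"),
         stratum_median = er_stratified_center(m, er, "median"))
}

#' @export
print.pam50_fit <- function(x, ...) {
  cat("Nearest-centroid intrinsic subtype fit\n")
  cat(sprintf("  %d samples classified over %d panel genes (%d excluded)\n",
              nrow(x$calls), length(x$genes_used), length(x$excluded)))
  cut <- if (inherits(x$er_cutoff, "er_cutoff")) x$er_cutoff$cutoff else x$er_cutoff
  cat(sprintf("  ER cutoff on %s: %.4f; ER+ fraction %.1f%%\n", x$er_gene,
              cut, 100 * mean(x$calls$er_status == "pos")))
  print(table(cohort = x$calls$cohort, subtype = x$calls$subtype))
  invisible(x)
}

#' Summarize a subtype fit
#'
#' Per-cohort subtype counts and proportions, ER-positive fractions, and
#' the median (IQR) of the assigned-subtype correlation per cohort and
#' subtype -- the standard cohort-description tables for this analysis.
#'
#' @param object A `pam50_fit`.
#' @param ... Unused.
#' @return List of data frames: `subtype_distribution`, `er_fraction`,
#'   `correlation_summary` (median and IQR of the correlation to the
#'   assigned centroid, by cohort and subtype).
#' @export
summary.pam50_fit <- function(object, ...) {
  calls <- object$calls
  st <- pam50_subtypes()
  dist <- as.data.frame(table(cohort = calls$cohort,
                              subtype = factor(calls$subtype, st)),
                        responseName = "n")
  dist$fraction <- stats::ave(dist$n, dist$cohort,
                              FUN = function(v) v / max(sum(v), 1))
  er <- stats::aggregate(list(er_pos_fraction = calls$er_status == "pos"),
                         by = list(cohort = calls$cohort), FUN = mean)
  own <- mapply(function(s, i) calls[[s]][i], calls$subtype,
                seq_len(nrow(calls)))
  cs <- do.call(rbind, lapply(split(data.frame(r = own, calls),
                                    list(calls$cohort, calls$subtype)),
                              function(d) {
    if (nrow(d) == 0) return(NULL)
    data.frame(cohort = d$cohort[1], subtype = d$subtype[1], n = nrow(d),
               median_r = stats::median(d$r),
               q1 = unname(stats::quantile(d$r, 0.25)),
               q3 = unname(stats::quantile(d$r, 0.75)))
  }))
  rownames(cs) <- NULL
  out <- list(subtype_distribution = dist, er_fraction = er,
              correlation_summary = cs)
  class(out) <- "summary.pam50_fit"
  out
}

#' @export
print.summary.pam50_fit <- function(x, ...) {
  cat("Subtype distribution by cohort:\n")
  print(x$subtype_distribution, row.names = FALSE)
  cat("\nER-positive fraction by cohort:\n")
  print(x$er_fraction, row.names = FALSE)
  cat("\nCorrelation to assigned centroid, median (IQR):\n")
  cs <- x$correlation_summary
  cs$summary <- sprintf("%.2f (%.2f-%.2f)", cs$median_r, cs$q1, cs$q3)
  print(cs[, c("cohort", "subtype", "n", "summary")], row.names = FALSE)
  invisible(x)
}

#' Classify new samples with a fitted subtype model
#'
#' Applies the stored ER cutoff, stratified centering and centroids to a
#' new z-scored gene x sample matrix. The new samples are centered within
#' their own ER strata (each stratum needs >= 2 samples).
#'
#' @param object A `pam50_fit`.
#' @param newdata Gene x sample matrix on z-score scale containing the ER
#'   gene and >= 3 panel genes.
#' @param ... Unused.
#' @return Data frame of calls in the same layout as `object$calls`.
#' @export
predict.pam50_fit <- function(object, newdata, ...) {
  er <- call_er_status(newdata, object$er_cutoff, esr1_gene = object$er_gene)
  centered <- apply_er_centering(newdata, er, object$center)
  correlations <- correlate_to_centroids(centered, object$centroids)
  assignment <- assign_subtype(correlations)
  data.frame(
    sample_id = assignment$sample_id,
    cohort = NA_character_,
    er_status = unname(er[assignment$sample_id]),
    correlations[assignment$sample_id, , drop = FALSE],
    subtype = assignment$subtype,
    margin = assignment$margin,
    tie_flag = assignment$tie_flag,
    stringsAsFactors = FALSE, row.names = NULL, check.names = FALSE)
}

#' Plot a subtype fit
#'
#' Two base-graphics panels: the ESR1 density with the estimated ER cutoff,
#' and per-subtype boxplots of the correlation to the assigned centroid.
#'
#' @param x A `pam50_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pam50_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  if (inherits(x$er_cutoff, "er_cutoff")) {
    d <- x$er_cutoff$density
    graphics::plot(d, main = paste(x$er_gene, "density"),
                   xlab = paste(x$er_gene, "(z-score)"), ...)
    graphics::abline(v = x$er_cutoff$cutoff, lty = 2, col = "red")
  }
  own <- mapply(function(s, i) x$calls[[s]][i], x$calls$subtype,
                seq_len(nrow(x$calls)))
  graphics::boxplot(own ~ factor(x$calls$subtype, pam50_subtypes()),
                    xlab = "assigned subtype",
                    ylab = "correlation to assigned centroid",
                    main = "Centroid correlation", las = 2)
  invisible(x)
}
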