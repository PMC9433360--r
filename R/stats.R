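# Association and comparison statistics: contingency-table construction
# from clinical annotation plus subtype calls, Fisher's exact r x c test
# (exact network enumeration with a Monte-Carlo fallback), Kruskal-Wallis,
# Mann-Whitney U, Pearson correlation, Cohen's kappa and complete-linkage
# hierarchical clustering. All tests are two-sided.

test_result <- function(test, statistic, p, method, ...) {
  structure(c(list(test = test, statistic = statistic, p = p,
                   method = method), list(...)), class = "assoc_test")
}

#' @export
print.assoc_test <- function(x, ...) {
  cat(sprintf("%s: ", x$test))
  if (!is.null(x$statistic) && is.finite(x$statistic)) {
    cat(sprintf("statistic = %.4g, ", x$statistic))
  }
  cat(sprintf("p = %.4g (%s)\n", x$p, x$method))
  invisible(x)
}

#' Cross-tabulate a clinical variable against subtype calls
#'
#' Builds the clinical-category x subtype contingency table over the
#' samples shared by the clinical table and the calls.
#'
#' @param clinical Clinical data frame with a `sample_id` column.
#' @param calls Data frame with `sample_id` and `subtype` columns (e.g.
#'   `fit$calls` from [pam50()]).
#' @param variable Clinical column to tabulate.
#' @param drop_na Drop samples with `NA` in `variable` (default `TRUE`);
#'   with `FALSE` they form an explicit `"NA"` row.
#' @return Integer matrix, categories x subtypes, margins conserving the
#'   shared sample count.
#' @export
build_contingency <- function(clinical, calls, variable, drop_na = TRUE) {
  .assert(variable %in% colnames(clinical),
          "unknown clinical variable: ", variable)
  common <- intersect(clinical$sample_id, calls$sample_id)
  .assert(length(common) > 0, "no samples shared by clinical table and calls")
  v <- clinical[[variable]][match(common, clinical$sample_id)]
  s <- calls$subtype[match(common, calls$sample_id)]
  if (drop_na) {
    keep <- !is.na(v)
    v <- v[keep]; s <- s[keep]
  } else {
    v[is.na(v)] <- "NA"
  }
  as.matrix(table(v, factor(s, pam50_subtypes()), dnn = NULL))
}

#' Fisher's exact test for r x c contingency tables
#'
#' For 2 x 2 tables, the classical two-sided exact test (sum of table
#' probabilities no larger than the observed one). For larger tables,
#' exact network enumeration is attempted first; if the table is too large
#' to enumerate (or `mode = "mc"`), the p-value is estimated by Monte-Carlo
#' sampling of tables with fixed margins under a fixed seed, reported with
#' its standard error and floored at `1 / (mc_reps + 1)` so it is never 0.
#'
#' @param table Non-negative integer matrix, at least 2 x 2.
#' @param mode `"auto"` (exact, falling back to Monte-Carlo), `"exact"`,
#'   or `"mc"`.
#' @param mc_reps Monte-Carlo replicates (default 1e6).
#' @param seed Seed for the Monte-Carlo draw (default 1).
#' @return An `assoc_test` result; Monte-Carlo results carry `mc_se`,
#'   `mc_reps` and `seed`.
#' @export
#' @examples
#' fisher_exact_rc(matrix(c(3, 0, 0, 3), 2))$p  # 0.1
#' tabs <- cmgt_clinical_tables()
#' fisher_exact_rc(t(tabs$lymph_node))
fisher_exact_rc <- function(table, mode = c("auto", "exact", "mc"),
                            mc_reps = 1e6, seed = 1) {
  mode <- match.arg(mode)
  tab <- as.matrix(table)
  .assert(all(tab >= 0) && all(tab == round(tab)),
          "counts must be non-negative integers")
  .assert(nrow(tab) >= 2 && ncol(tab) >= 2, "table must be at least 2 x 2")
  .assert(all(rowSums(tab) > 0) && all(colSums(tab) > 0),
          "degenerate table: zero row or column margin")
  n <- sum(tab)
  run_mc <- function() {
    res <- with_seed(seed, stats::fisher.test(tab, simulate.p.value = TRUE,
                                              B = mc_reps))
    p <- max(res$p.value, 1 / (mc_reps + 1))
    test_result("Fisher exact (r x c)", NA_real_, p,
                sprintf("Monte-Carlo, %g replicates, seed %d", mc_reps,
                        as.integer(seed)),
                mc_se = sqrt(p * (1 - p) / mc_reps),
                mc_reps = mc_reps, seed = as.integer(seed),
                table_dim = dim(tab))
  }
  if (mode == "mc") return(run_mc())
  exact <- tryCatch(
    stats::fisher.test(tab, workspace = 2e7),
    error = function(e) NULL)
  if (is.null(exact)) {
    .assert(mode != "exact",
            "table too large for exact enumeration; use mode = 'mc'")
    return(run_mc())
  }
  test_result("Fisher exact (r x c)", NA_real_, exact$p.value,
              if (all(dim(tab) == 2)) "exact hypergeometric"
              else "exact network enumeration",
              table_dim = dim(tab))
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with the chi-square approximation, two-sided.
#'
#' @param groups List of numeric vectors (>= 2 groups, each >= 2 values).
#' @return An `assoc_test` result with the H statistic.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))$statistic  # 3.857...
kruskal_wallis <- function(groups) {
  .assert(is.list(groups) && length(groups) >= 2, "need >= 2 groups")
  .assert(all(vapply(groups, length, integer(1)) >= 2),
          "each group needs >= 2 values")
  vals <- unlist(groups, use.names = FALSE)
  .assert(length(unique(vals)) > 1,
          "all values identical; the tie correction is degenerate")
  res <- stats::kruskal.test(groups)
  test_result("Kruskal-Wallis", unname(res$statistic), res$p.value,
              sprintf("chi-square approximation, df = %d",
                      unname(res$parameter)),
              group_sizes = vapply(groups, length, integer(1)))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two samples: exact null enumeration
#' when the combined sample is small and untied, otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param a,b Numeric vectors (non-empty).
#' @param exact_threshold Use the exact null when `length(a) + length(b)`
#'   is at most this and there are no ties (default 50).
#' @return An `assoc_test` result with the U statistic.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p  # exact 0.1
mann_whitney_u <- function(a, b, exact_threshold = 50) {
  .assert(length(a) > 0 && length(b) > 0, "both groups must be non-empty")
  ties <- any(duplicated(c(a, b)))
  use_exact <- !ties && (length(a) + length(b)) <= exact_threshold
  res <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE))
  test_result("Mann-Whitney U", unname(res$statistic), res$p.value,
              if (use_exact) "exact null enumeration"
              else "normal approximation with tie correction",
              group_sizes = c(length(a), length(b)))
}

#' Pearson correlation test
#'
#' Pearson's r with the two-sided t-based p-value.
#'
#' @param x,y Paired numeric vectors (>= 3 finite pairs, non-zero
#'   variance).
#' @return An `assoc_test` result; `statistic` is r, with `n` the pair
#'   count.
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  .assert(length(x) >= 3, "need at least 3 finite pairs")
  .assert(stats::sd(x) > 0 && stats::sd(y) > 0, "zero variance input")
  res <- stats::cor.test(x, y, method = "pearson")
  test_result("Pearson correlation", unname(res$estimate), res$p.value,
              "two-sided t test", n = length(x))
}

#' Cohen's kappa from a square agreement table
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` between two
#' categorical labelings.
#'
#' @param table Square count matrix (rows: rater A, columns: rater B).
#' @return An `assoc_test` result; `statistic` is kappa (no p-value is
#'   attached).
#' @export
#' @examples
#' cohen_kappa(matrix(c(20, 10, 5, 15), 2))$statistic  # 0.4
cohen_kappa <- function(table) {
  tab <- as.matrix(table)
  .assert(nrow(tab) == ncol(tab), "agreement table must be square")
  k <- kappa_from_table(tab)
  test_result("Cohen's kappa", k, NA_real_, "unweighted", n = sum(tab))
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering on Euclidean distances with complete linkage --
#' the standard ordering step for expression heatmaps. Ties in merge
#' heights are resolved deterministically by input order (the behavior of
#' [stats::hclust()]).
#'
#' @param m Numeric matrix.
#' @param axis Cluster `"rows"` (default) or `"cols"`.
#' @return List with `order` (leaf labels in dendrogram order) and
#'   `tree` (the `hclust` object).
#' @export
hierarchical_cluster <- function(m, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  x <- if (axis == "rows") m else t(m)
  .assert(nrow(x) >= 2, "need at least two items to cluster")
  d <- stats::dist(x, method = "euclidean")
  .assert(all(is.finite(d)), "non-finite distances")
  hc <- stats::hclust(d, method = "complete")
  list(order = rownames(x)[hc$order] %||% hc$order, tree = hc)
}

#' Render the standard report tables
#'
#' Emits the clinical-by-subtype summary (one contingency table and Fisher
#' p-value per clinical variable, empty subtype classes kept as zero
#' columns) and the per-subtype median (IQR) correlation summary, and
#' optionally writes them as TSV plus a small markdown digest.
#'
#' @param fit A `pam50_fit`.
#' @param clinical Clinical data frame (optional).
#' @param variables Clinical columns to tabulate (default all but
#'   `sample_id`).
#' @param out Output directory; created if needed. `NULL` (default) writes
#'   nothing.
#' @return List with `clinical_tables` (named list of matrices),
#'   `clinical_tests` (data frame of Fisher p-values),
#'   `correlation_summary` and `subtype_distribution` (from
#'   [summary.pam50_fit()]).
#' @export
render_report <- function(fit, clinical = NULL, variables = NULL,
                          out = NULL) {
  sm <- summary(fit)
  res <- list(clinical_tables = list(), clinical_tests = NULL,
              correlation_summary = sm$correlation_summary,
              subtype_distribution = sm$subtype_distribution)
  if (!is.null(clinical)) {
    if (is.null(variables)) {
      variables <- setdiff(colnames(clinical), "sample_id")
    }
    tests <- lapply(variables, function(v) {
      tab <- build_contingency(clinical, fit$calls, v, drop_na = TRUE)
      res$clinical_tables[[v]] <<- tab
      usable <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
      p <- if (nrow(usable) >= 2 && ncol(usable) >= 2) {
        fisher_exact_rc(usable)$p
      } else {
        NA_real_
      }
      data.frame(variable = v, n = sum(tab), p = p,
                 stringsAsFactors = FALSE)
    })
    res$clinical_tests <- do.call(rbind, tests)
  }
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(fit$calls, file.path(out, "subtype_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$correlation_summary,
                       file.path(out, "correlation_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    md <- c("# Subtype report", "",
            "## Subtype distribution",
            utils::capture.output(print(res$subtype_distribution,
                                        row.names = FALSE)))
    if (!is.null(res$clinical_tests)) {
      utils::write.table(res$clinical_tests,
                         file.path(out, "clinical_tests.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      md <- c(md, "", "## Clinical associations (Fisher exact)",
              utils::capture.output(print(res$clinical_tests,
                                          row.names = FALSE)))
    }
    writeLines(md, file.path(out, "report.md"))
  }
  res
}
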