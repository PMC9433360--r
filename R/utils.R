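# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

.stop <- function(...) stop(..., call. = FALSE)

.assert <- function(cond, ...) if (!isTRUE(cond)) .stop(...)

#' Canonical intrinsic subtype labels
#'
#' The four intrinsic molecular subtypes used throughout the package, in
#' canonical order. This order also defines the deterministic tie-break in
#' [assign_subtype()]: on a tied maximum correlation the earlier label wins.
#'
#' @return Character vector of length four:
#'   `"Basal-like"`, `"HER2-enriched"`, `"Luminal A"`, `"Luminal B"`.
#' @export
#' @examples
#' pam50_subtypes()
pam50_subtypes <- function() {
  c("Basal-like", "HER2-enriched", "Luminal A", "Luminal B")
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Expression-matrix metadata. Matrices travel as plain numeric gene x sample
# matrices; the cohort tag and the expression scale ("linear", "log2",
# "zscore") ride along as attributes so transforms can refuse to double-log.
expr_matrix <- function(values, cohort = NA_character_,
                        scale = c("linear", "log2", "zscore")) {
  scale <- match.arg(scale)
  .assert(is.matrix(values) && is.numeric(values),
          "expression values must form a numeric matrix")
  .assert(!is.null(rownames(values)), "expression matrix needs gene rownames")
  .assert(!is.null(colnames(values)), "expression matrix needs sample colnames")
  .assert(!anyDuplicated(rownames(values)), "duplicate gene symbols")
  attr(values, "cohort") <- cohort
  attr(values, "scale") <- scale
  values
}

expr_scale <- function(m) attr(m, "scale") %||% "linear"
expr_cohort <- function(m) attr(m, "cohort") %||% NA_character_

# Copy expression metadata (and any flags in `extra`) onto a derived matrix.
carry_meta <- function(new, old, scale = expr_scale(old), extra = list()) {
  attr(new, "cohort") <- expr_cohort(old)
  attr(new, "scale") <- scale
  for (nm in names(extra)) attr(new, nm) <- extra[[nm]]
  new
}

# Per-sample cohort tags of a merged matrix.
merged_cohorts <- function(m) {
  ch <- attr(m, "cohorts")
  .assert(!is.null(ch) && length(ch) == ncol(m),
          "matrix carries no per-sample cohort tags; run intersect_and_merge()")
  ch
}
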