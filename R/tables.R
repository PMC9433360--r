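#' Clinical cross-tabulations of the 157-tumor canine mammary cohort
#'
#' Published cross-tabulations of PAM50 subtype against clinical
#' characteristics for the 157 canine mammary gland tumors of the GSE119810
#' cohort (42 basal-like, 14 HER2-enriched, 92 luminal A, 9 luminal B).
#' These printed count tables are the inputs for the association tests in
#' [fisher_exact_rc()]; they are transcribed here so the tests can be rerun
#' without re-deriving subtype calls from the accession data.
#'
#' Grade is recorded for the 112 histopathologically malignant tumors only;
#' the `neuter` table carries an explicit `"NA"` row (3 dogs with unknown
#' status) which association tests conventionally drop.
#'
#' @return A named list of integer matrices, one per clinical variable
#'   (`histology` 5x4, `grade` 3x4, `lymph_node` 2x4, `neuter` 3x4), each
#'   with clinical categories as rows and the four subtypes
#'   ([pam50_subtypes()]) as columns.
#' @export
#' @examples
#' tabs <- cmgt_clinical_tables()
#' colSums(tabs$histology)   # subtype totals: 42 14 92 9
#' fisher_exact_rc(tabs$lymph_node)
cmgt_clinical_tables <- function() {
  st <- pam50_subtypes()
  mk <- function(counts, rows) {
    matrix(as.integer(counts), nrow = length(rows), byrow = TRUE,
           dimnames = list(rows, st))
  }
  list(
    histology = mk(c(6, 5, 31, 3,
                     4, 1, 8, 0,
                     6, 1, 26, 0,
                     23, 7, 25, 3,
                     3, 0, 2, 3),
                   c("Benign", "Mixed tumor", "Complex carcinoma",
                     "Simple carcinoma", "Other histology")),
    grade = mk(c(7, 4, 48, 2,
                 9, 4, 8, 2,
                 20, 1, 5, 2),
               c("1", "2", "3")),
    lymph_node = mk(c(30, 13, 89, 9,
                      12, 1, 3, 0),
                    c("Absent", "Present")),
    neuter = mk(c(26, 10, 63, 6,
                  15, 4, 28, 2,
                  1, 0, 1, 1),
                c("Intact", "Neutered", "NA"))
  )
}
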