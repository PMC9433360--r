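# Readers and writers for the on-disk formats the pipeline touches:
# expression TSV (first column gene symbol, header row of sample IDs),
# clinical TSV, SEG, variant TSV (exported from a VEP-annotated VCF),
# GMT gene sets, and a two-column ortholog map. All plain text; the
# synthetic generator writes exactly what these readers read.

#' Read a gene x sample expression table
#'
#' Tab-separated, first column gene symbols, header row of sample IDs.
#' Duplicate gene rows are collapsed by their mean with a warning; `NA`
#' cells become missing values; any other non-numeric cell is a parse error
#' reported with its row and column.
#'
#' @param path File path.
#' @param cohort_tag Free-text cohort tag stored on the matrix (e.g.
#'   `"CMGT"`, `"TCGA"`).
#' @param scale Declared expression scale (`"linear"` FPKM, `"log2"`, or
#'   `"zscore"`).
#' @return Numeric gene x sample matrix with `cohort` and `scale`
#'   attributes.
#' @export
read_expression_table <- function(path, cohort_tag = NA_character_,
                                  scale = c("linear", "log2", "zscore")) {
  scale <- match.arg(scale)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  .assert(nrow(raw) > 0 && ncol(raw) >= 2,
          "empty or malformed expression table: ", path)
  genes <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals),
                                dimnames = dimnames(vals)))
  bad <- which(is.na(num) & !is.na(vals) & trimws(vals) != "NA", arr.ind = TRUE)
  if (nrow(bad) > 0) {
    .stop(sprintf("non-numeric cell '%s' at gene row %d, sample column '%s'",
                  vals[bad[1, 1], bad[1, 2]], bad[1, 1],
                  colnames(vals)[bad[1, 2]]))
  }
  rownames(num) <- genes
  num <- collapse_duplicate_genes(num)
  expr_matrix(num, cohort = cohort_tag, scale = scale)
}

# Mean-collapse duplicated gene symbols (symmetric, scale-preserving).
collapse_duplicate_genes <- function(m) {
  if (!anyDuplicated(rownames(m))) return(m)
  dups <- unique(rownames(m)[duplicated(rownames(m))])
  warning(sprintf("%d duplicated gene symbol(s) collapsed by mean: %s",
                  length(dups), paste(utils::head(dups, 5), collapse = ", ")),
          call. = FALSE)
  f <- factor(rownames(m), levels = unique(rownames(m)))
  counts <- as.vector(table(f))
  out <- rowsum(m, f, reorder = FALSE) / counts
  rownames(out) <- levels(f)
  out
}

#' Write an expression table
#'
#' Inverse of [read_expression_table()]: the round trip reproduces the
#' matrix exactly (modulo numeric formatting).
#' @param m Gene x sample matrix.
#' @param path Output path.
#' @export
write_expression_table <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a subtype-centroid table
#'
#' TSV with a gene column followed by exactly four subtype columns, which
#' are reordered to the canonical order of [pam50_subtypes()]. A table with
#' extra subtype columns (e.g. a normal-like column) is rejected by name:
#' the classifier is defined for the four main intrinsic subtypes only.
#'
#' @param path File path.
#' @return Gene x 4 numeric centroid matrix in canonical column order.
#' @export
read_centroids <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  .assert(nrow(raw) > 0, "empty centroid table: ", path)
  cols <- colnames(raw)[-1]
  canon <- pam50_subtypes()
  extra <- setdiff(cols, canon)
  missing <- setdiff(canon, cols)
  if (length(extra) > 0 || length(missing) > 0) {
    .stop("centroid table must have exactly the four subtype columns (",
          paste(canon, collapse = ", "), ")",
          if (length(extra) > 0)
            paste0("; unexpected column(s): ", paste(extra, collapse = ", ")),
          if (length(missing) > 0)
            paste0("; missing column(s): ", paste(missing, collapse = ", ")))
  }
  m <- as.matrix(raw[, canon, drop = FALSE])
  .assert(is.numeric(m), "centroid values must be numeric")
  rownames(m) <- as.character(raw[[1]])
  .assert(!anyDuplicated(rownames(m)), "duplicate gene symbols in centroids")
  m
}

#' Write a centroid table
#' @param centroids Gene x 4 matrix.
#' @param path Output path.
#' @export
write_centroids <- function(centroids, path) {
  df <- data.frame(gene = rownames(centroids), centroids,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SEG-style segmented copy-number table
#'
#' Expects columns sample, chrom, start, end, seg.mean (any of the common
#' header spellings; otherwise the first five columns are used positionally).
#' Coordinates are treated as 1-based inclusive. Overlapping segments
#' within one sample and chromosome are an error naming the first
#' offending pair.
#'
#' @param path File path.
#' @return Data frame `sample_id`, `chrom`, `start`, `end`, `seg_mean`.
#' @export
read_seg <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  .assert(ncol(raw) >= 5, "SEG file needs >= 5 columns: ", path)
  pick <- function(cands, fallback) {
    hit <- match(tolower(cands), tolower(colnames(raw)))
    hit <- hit[!is.na(hit)]
    if (length(hit) > 0) hit[1] else fallback
  }
  seg <- data.frame(
    sample_id = as.character(raw[[pick(c("sample", "sample_id", "id"), 1)]]),
    chrom = as.character(raw[[pick(c("chrom", "chr", "chromosome"), 2)]]),
    start = as.numeric(raw[[pick(c("start", "loc.start"), 3)]]),
    end = as.numeric(raw[[pick(c("end", "loc.end"), 4)]]),
    seg_mean = as.numeric(raw[[pick(c("seg.mean", "seg_mean", "segmean"), 5)]]),
    stringsAsFactors = FALSE)
  validate_segments(seg)
  seg
}

validate_segments <- function(seg) {
  .assert(all(is.finite(seg$start)) && all(is.finite(seg$end)),
          "segment coordinates must be numeric")
  .assert(all(seg$start <= seg$end), "segment start must be <= end")
  for (key in split(seq_len(nrow(seg)),
                    paste(seg$sample_id, seg$chrom, sep = "\r"))) {
    if (length(key) < 2) next
    o <- key[order(seg$start[key])]
    lap <- which(seg$start[o][-1] <= seg$end[o][-length(o)])
    if (length(lap) > 0) {
      i <- o[lap[1]]; j <- o[lap[1] + 1]
      .stop(sprintf(
        "overlapping segments for sample %s on %s: [%d, %d] and [%d, %d]",
        seg$sample_id[i], seg$chrom[i], seg$start[i], seg$end[i],
        seg$start[j], seg$end[j]))
    }
  }
  invisible(seg)
}

#' Write a SEG table
#' @param seg Segment data frame from [read_seg()] or [simulate_segments()].
#' @param path Output path.
#' @export
write_seg <- function(seg, path) {
  utils::write.table(seg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# VEP consequence vocabulary accepted without comment; unknown terms are
# kept with a warning (filtering happens downstream, not at ingest).
consequence_vocabulary <- function() {
  c("missense_variant", "synonymous_variant", "stop_gained", "stop_lost",
    "start_lost", "frameshift_variant", "inframe_insertion",
    "inframe_deletion", "splice_acceptor_variant", "splice_donor_variant",
    "splice_region_variant", "intron_variant", "upstream_gene_variant",
    "downstream_gene_variant", "5_prime_UTR_variant", "3_prime_UTR_variant",
    "stop_retained_variant", "coding_sequence_variant",
    "protein_altering_variant", "intergenic_variant")
}

#' Read a consequence-annotated variant table
#'
#' TSV export of a VEP-annotated VCF with (at least) sample, gene and
#' Consequence columns. Rows with consequence terms outside the known VEP
#' vocabulary are kept with a warning; consequence-based filtering is the
#' job of [filter_mutations()].
#'
#' @param path File path.
#' @return Data frame `sample_id`, `gene`, `consequence`.
#' @export
read_variant_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  pick <- function(cands, fallback) {
    hit <- match(tolower(cands), tolower(colnames(raw)))
    hit <- hit[!is.na(hit)]
    if (length(hit) > 0) hit[1] else fallback
  }
  out <- data.frame(
    sample_id = as.character(raw[[pick(c("sample", "sample_id"), 1)]]),
    gene = as.character(raw[[pick(c("gene", "symbol", "gene_symbol"), 2)]]),
    consequence = as.character(raw[[pick(c("consequence", "csq"), 3)]]),
    stringsAsFactors = FALSE)
  unknown <- setdiff(unique(out$consequence), consequence_vocabulary())
  if (length(unknown) > 0) {
    warning("unknown consequence term(s) kept: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  out
}

#' Write a variant table
#' @param variants Data frame `sample_id`, `gene`, `consequence`.
#' @param path Output path.
#' @export
write_variant_table <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a clinical annotation table
#'
#' TSV with columns `sample_id`, `histology`, `grade`, `lymph_node`,
#' `neuter`. Histology must use the five combined categories; other
#' categorical columns are validated against their controlled levels,
#' with `NA` allowed everywhere except `sample_id`.
#'
#' @param path File path.
#' @return Validated clinical data frame.
#' @export
read_clinical_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE,
                           colClasses = "character")
  need <- c("sample_id", "histology", "grade", "lymph_node", "neuter")
  .assert(all(need %in% colnames(raw)),
          "clinical table must have columns: ", paste(need, collapse = ", "))
  out <- raw[, need]
  .assert(!anyDuplicated(out$sample_id), "duplicate sample_id in clinical table")
  chk <- function(col, levels) {
    bad <- setdiff(stats::na.omit(unique(out[[col]])), levels)
    .assert(length(bad) == 0,
            sprintf("unknown %s value(s): %s", col, paste(bad, collapse = ", ")))
  }
  chk("histology", c("Simple carcinoma", "Complex carcinoma", "Mixed tumor",
                     "Benign", "Other histology"))
  chk("grade", c("1", "2", "3"))
  chk("lymph_node", c("Absent", "Present"))
  chk("neuter", c("Intact", "Neutered"))
  out
}

#' Write a clinical table
#' @param clinical Clinical data frame.
#' @param path Output path.
#' @export
write_clinical_table <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member symbols, tab-separated.
#' Duplicate members within a set are dropped.
#'
#' @param path File path.
#' @return Named list of gene sets; each element is a list with `name`,
#'   `description` and `members` (unique character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  .assert(length(lines) > 0, "empty GMT file: ", path)
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    .assert(length(parts) >= 3, "GMT line needs name, description, >=1 member")
    list(name = parts[1], description = parts[2],
         members = unique(parts[-(1:2)]))
  })
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}

#' Write gene sets in GMT format
#' @param genesets Named list as returned by [read_gmt()].
#' @param path Output path.
#' @export
write_gmt <- function(genesets, path) {
  lines <- vapply(genesets, function(gs) {
    paste(c(gs$name, gs$description, gs$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column ortholog symbol map
#'
#' @param path TSV with source symbols in column 1 and target symbols in
#'   column 2 (header optional, detected by a `source`/`target`-like first
#'   line).
#' @return Data frame `source`, `target`.
#' @export
read_ortholog_map <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character")
  .assert(ncol(raw) >= 2, "ortholog map needs two columns")
  if (tolower(raw[1, 1]) %in% c("source", "from", "canine", "gene")) {
    raw <- raw[-1, , drop = FALSE]
  }
  data.frame(source = raw[[1]], target = raw[[2]], stringsAsFactors = FALSE)
}

#' Map expression-matrix gene symbols into an ortholog namespace
#'
#' Renames each mapped gene to its target-species symbol. Genes without a
#' map entry keep their original symbol and are flagged in the returned
#' matrix's `"unmapped"` attribute. When several source genes map to the
#' same target symbol (or a mapped symbol collides with an existing one),
#' the rows are collapsed by their mean with a warning.
#'
#' @param m Gene x sample expression matrix.
#' @param map Data frame from [read_ortholog_map()]; an empty map is the
#'   identity.
#' @return Mapped matrix with the same metadata.
#' @export
map_orthologs <- function(m, map) {
  if (nrow(map) == 0) return(m)
  .assert(!anyDuplicated(map$source), "ortholog map has duplicate source symbols")
  idx <- match(rownames(m), map$source)
  new_names <- ifelse(is.na(idx), rownames(m), map$target[idx])
  unmapped <- rownames(m)[is.na(idx)]
  out <- m
  rownames(out) <- new_names
  out <- collapse_duplicate_genes(out)
  carry_meta(out, m, extra = list(unmapped = unmapped))
}
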