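# Mutation and copy-number characterization: non-synonymous filtering with
# FLAGS exclusion, tumor mutation burden and recurrence; segment-level
# amplification/deletion calls at the +-0.2 segment-mean thresholds, the
# per-tumor aberration index, gene-level copy number by longest-overlap
# segment, and per-subtype aberration frequencies along a binned genome.

#' Default FLAGS exclusion list
#'
#' The ten FLAGS (FrequentLy mutAted GeneS) most often seen in exome
#' studies -- large genes whose recurrent mutations are routinely treated
#' as likely passengers or artifacts and excluded from burden analyses.
#' The list is configuration, not a fixed constant: pass any vector to
#' [filter_mutations()].
#'
#' @return Character vector of 10 gene symbols.
#' @export
flags_genes <- function() {
  c("TTN", "MUC16", "OBSCN", "AHNAK2", "SYNE1",
    "FLG", "MUC5B", "DNAH17", "PLEC", "DST")
}

#' Default non-synonymous coding consequence classes
#'
#' VEP consequence terms retained by [filter_mutations()] as
#' protein-altering coding changes.
#'
#' @return Character vector of consequence terms.
#' @export
nonsynonymous_classes <- function() {
  c("missense_variant", "stop_gained", "stop_lost", "start_lost",
    "frameshift_variant", "inframe_insertion", "inframe_deletion",
    "splice_acceptor_variant", "splice_donor_variant")
}

#' Filter a mutation table to non-synonymous coding variants
#'
#' Keeps rows whose consequence is in `keep_classes` and whose gene is not
#' in `flags`; the removed-row counts per reason are attached as attribute
#' `"removed"`. The operation is idempotent.
#'
#' @param variants Data frame `sample_id`, `gene`, `consequence`.
#' @param flags Genes to exclude (default [flags_genes()]).
#' @param keep_classes Consequence classes to retain (default
#'   [nonsynonymous_classes()]).
#' @return Filtered data frame.
#' @export
filter_mutations <- function(variants, flags = flags_genes(),
                             keep_classes = nonsynonymous_classes()) {
  .assert(length(keep_classes) > 0, "keep_classes must be non-empty")
  class_ok <- variants$consequence %in% keep_classes
  flags_hit <- variants$gene %in% flags
  keep <- class_ok & !flags_hit
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(class = sum(!class_ok),
                            FLAGS = sum(class_ok & flags_hit))
  out
}

#' Tumor mutation burden
#'
#' Number of (filtered) mutation rows per tumor. The full sample list must
#' be supplied so tumors with zero retained mutations are counted
#' explicitly.
#'
#' @param variants Filtered mutation table (see [filter_mutations()]).
#' @param samples Character vector of all sample IDs.
#' @return Named integer vector, one count (>= 0) per sample.
#' @export
tmb <- function(variants, samples) {
  counts <- table(factor(variants$sample_id, levels = samples))
  stats::setNames(as.integer(counts), samples)
}

#' Recurrently mutated genes
#'
#' Genes mutated in at least `min_tumors` distinct tumors. Multiple
#' mutations of one gene in one tumor count once toward the tumor tally.
#'
#' @param variants Filtered mutation table.
#' @param min_tumors Minimum number of distinct mutated tumors (default 4).
#' @param subtypes Optional named vector mapping sample_id to subtype; when
#'   given, per-subtype tumor counts are included.
#' @return Data frame `gene`, `n_tumors` (plus one count column per subtype
#'   when `subtypes` is given), ordered by decreasing `n_tumors`.
#' @export
recurrent_genes <- function(variants, min_tumors = 4, subtypes = NULL) {
  .assert(min_tumors >= 1, "min_tumors must be >= 1")
  uniq <- unique(variants[, c("sample_id", "gene")])
  counts <- table(uniq$gene)
  keep <- names(counts)[counts >= min_tumors]
  out <- data.frame(gene = keep,
                    n_tumors = as.integer(counts[keep]),
                    stringsAsFactors = FALSE)
  if (!is.null(subtypes)) {
    st <- pam50_subtypes()
    per <- table(factor(uniq$gene, levels = keep),
                 factor(subtypes[uniq$sample_id], levels = st))
    out <- cbind(out, as.data.frame.matrix(per))
  }
  out <- out[order(-out$n_tumors, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call segment-level copy-number aberrations
#'
#' A segment is amplified iff its segment mean is strictly greater than
#' `amp_cut` and deleted iff strictly less than `del_cut`; otherwise
#' neutral. Defaults are the standard +-0.2 log-ratio thresholds.
#'
#' @param segments SEG-style data frame (`sample_id`, `chrom`, `start`,
#'   `end`, `seg_mean`).
#' @param amp_cut,del_cut Amplification and deletion thresholds
#'   (`amp_cut > del_cut`).
#' @return The segment table with an added `call` column
#'   (`"amp"`/`"del"`/`"neutral"`).
#' @export
call_segment_aberrations <- function(segments, amp_cut = 0.2,
                                     del_cut = -0.2) {
  .assert(amp_cut > del_cut, "amp_cut must exceed del_cut")
  segments$call <- ifelse(segments$seg_mean > amp_cut, "amp",
                          ifelse(segments$seg_mean < del_cut, "del",
                                 "neutral"))
  segments
}

#' Copy-number aberration index
#'
#' Per tumor, the fraction of the covered genome (sum of segment lengths,
#' 1-based inclusive) lying in amplified or deleted segments. Always in
#' `[0, 1]`, and 0 exactly when no segment is called aberrant.
#'
#' @param calls Segment table with a `call` column
#'   (see [call_segment_aberrations()]).
#' @return Named numeric vector, one index per sample.
#' @export
aberration_index <- function(calls) {
  .assert("call" %in% colnames(calls),
          "segments must carry calls; run call_segment_aberrations()")
  len <- calls$end - calls$start + 1
  tot <- tapply(len, calls$sample_id, sum)
  .assert(all(tot > 0), "zero total segment length for some sample")
  ab <- tapply(len * (calls$call != "neutral"), calls$sample_id, sum)
  idx <- ab / tot
  stats::setNames(as.numeric(idx), names(tot))
}

#' Gene-level copy number from segments
#'
#' Assigns each gene, per sample, the segment mean of the overlapping
#' segment with the longest overlap (with `method = "weighted"`, the
#' overlap-length-weighted mean of all overlapping segments). Genes with no
#' overlapping segment are missing for that sample.
#'
#' @param segments SEG-style data frame, 1-based inclusive coordinates.
#' @param genes Data frame `gene`, `chrom`, `start`, `end` (1-based
#'   inclusive; a 0-based BED input must be shifted by +1 first).
#' @param amp_cut,del_cut Call thresholds, as in
#'   [call_segment_aberrations()].
#' @param method `"longest"` (default) or `"weighted"`.
#' @return Data frame `sample_id`, `gene`, `seg_mean`, `call` (one row per
#'   sample x gene with any overlap).
#' @export
gene_copy_number <- function(segments, genes, amp_cut = 0.2, del_cut = -0.2,
                             method = c("longest", "weighted")) {
  method <- match.arg(method)
  .assert(all(genes$start <= genes$end), "gene start must be <= end")
  res <- lapply(split(segments, segments$sample_id), function(seg) {
    hits <- lapply(unique(genes$chrom), function(ch) {
      g <- genes[genes$chrom == ch, , drop = FALSE]
      s <- seg[seg$chrom == ch, , drop = FALSE]
      if (nrow(g) == 0 || nrow(s) == 0) return(NULL)
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(g$start, g$end),
        IRanges::IRanges(s$start, s$end))
      if (length(ov) == 0) return(NULL)
      gi <- S4Vectors::queryHits(ov)
      si <- S4Vectors::subjectHits(ov)
      width <- pmin(g$end[gi], s$end[si]) - pmax(g$start[gi], s$start[si]) + 1
      data.frame(gene = g$gene[gi], seg_mean = s$seg_mean[si],
                 overlap = width, stringsAsFactors = FALSE)
    })
    hits <- do.call(rbind, hits)
    if (is.null(hits)) return(NULL)
    per_gene <- lapply(split(hits, hits$gene), function(h) {
      sm <- if (method == "longest") {
        h$seg_mean[which.max(h$overlap)]
      } else {
        sum(h$seg_mean * h$overlap) / sum(h$overlap)
      }
      data.frame(sample_id = seg$sample_id[1], gene = h$gene[1],
                 seg_mean = sm, stringsAsFactors = FALSE)
    })
    do.call(rbind, per_gene)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  out <- if (length(res) > 0) {
    do.call(rbind, c(res, list(make.row.names = FALSE)))
  } else {
    data.frame(sample_id = character(), gene = character(),
               seg_mean = numeric(), stringsAsFactors = FALSE)
  }
  out$call <- ifelse(out$seg_mean > amp_cut, "amp",
                     ifelse(out$seg_mean < del_cut, "del", "neutral"))
  rownames(out) <- NULL
  out
}

#' Per-subtype aberration frequency along a binned genome
#'
#' Tiles each chromosome into `bin_size` bins and reports, for every bin
#' and subtype, the fraction of that subtype's samples with an amplified
#' (resp. deleted) segment overlapping the bin.
#'
#' @param calls Segment table with `call` column.
#' @param subtypes Named vector mapping every sample_id in `calls` to a
#'   subtype; unlabeled samples are an error.
#' @param bin_size Bin width in bp (default 5e6).
#' @return Data frame `chrom`, `start`, `end`, `subtype`, `amp_freq`,
#'   `del_freq`, frequencies in `[0, 1]`.
#' @export
subtype_cn_frequency <- function(calls, subtypes, bin_size = 5e6) {
  miss <- setdiff(unique(calls$sample_id), names(subtypes))
  .assert(length(miss) == 0, "unlabeled sample(s): ",
          paste(utils::head(miss, 5), collapse = ", "))
  n_per <- table(subtypes[unique(calls$sample_id)])
  bins <- do.call(rbind, lapply(split(calls, calls$chrom), function(s) {
    top <- max(s$end)
    starts <- seq(1, top, by = bin_size)
    data.frame(chrom = s$chrom[1], start = starts,
               end = pmin(starts + bin_size - 1, top),
               stringsAsFactors = FALSE)
  }))
  rownames(bins) <- NULL
  ab <- calls[calls$call != "neutral", , drop = FALSE]
  out <- lapply(names(n_per), function(st) {
    res <- bins
    res$subtype <- st
    res$amp_freq <- 0
    res$del_freq <- 0
    sub <- ab[subtypes[ab$sample_id] == st, , drop = FALSE]
    if (nrow(sub) > 0) {
      for (i in seq_len(nrow(res))) {
        hit <- sub$chrom == res$chrom[i] & sub$start <= res$end[i] &
          sub$end >= res$start[i]
        res$amp_freq[i] <-
          length(unique(sub$sample_id[hit & sub$call == "amp"])) / n_per[[st]]
        res$del_freq[i] <-
          length(unique(sub$sample_id[hit & sub$call == "del"])) / n_per[[st]]
      }
    }
    res
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}
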