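# Mutation filtering/burden/recurrence and copy-number calls, aberration
# index and gene-level assignment against brute-force oracles.

toy_variants <- function() {
  data.frame(
    sample_id = c("T1", "T1", "T2", "T2", "T3"),
    gene = c("TP53", "TTN", "PIK3CA", "BRCA1", "BRCA1"),
    consequence = c("missense_variant", "missense_variant",
                    "synonymous_variant", "missense_variant",
                    "synonymous_variant"),
    stringsAsFactors = FALSE)
}

test_that("mutation filter removes by class and FLAGS, and is idempotent", {
  v <- toy_variants()
  f <- filter_mutations(v)
  expect_identical(nrow(f), 2L)  # TP53 missense + BRCA1 missense survive
  expect_setequal(f$gene, c("TP53", "BRCA1"))
  expect_identical(attr(f, "removed"), c(class = 2L, FLAGS = 1L))
  expect_equal(filter_mutations(f), f, ignore_attr = TRUE)
  expect_error(filter_mutations(v, keep_classes = character()), "non-empty")
})

test_that("TMB counts rows per tumor, including explicit zeros", {
  f <- filter_mutations(toy_variants())
  counts <- tmb(f, samples = c("T1", "T2", "T3", "T4"))
  expect_identical(counts, c(T1 = 1L, T2 = 1L, T3 = 0L, T4 = 0L))
  expect_identical(sum(counts), nrow(f))  # conservation

  three <- data.frame(sample_id = "T9", gene = c("A", "B", "C"),
                      consequence = "missense_variant")
  expect_identical(unname(tmb(three, "T9")), 3L)
})

test_that("recurrence counts distinct tumors, not mutation rows", {
  v <- data.frame(
    sample_id = c("T1", "T2", "T3", "T4", rep("T5", 5)),
    gene = c(rep("PIK3CA", 4), rep("KMT2D", 5)),
    consequence = "missense_variant", stringsAsFactors = FALSE)
  rec <- recurrent_genes(v, min_tumors = 4)
  expect_identical(rec$gene, "PIK3CA")  # KMT2D: 5 mutations in 1 tumor
  expect_identical(rec$n_tumors, 4L)

  # brute-force enumeration oracle on a random toy table
  set.seed(30)
  big <- data.frame(
    sample_id = sample(paste0("T", 1:12), 60, replace = TRUE),
    gene = sample(LETTERS[1:6], 60, replace = TRUE),
    consequence = "missense_variant", stringsAsFactors = FALSE)
  rec2 <- recurrent_genes(big, min_tumors = 3)
  oracle <- sapply(LETTERS[1:6], function(g) {
    length(unique(big$sample_id[big$gene == g]))
  })
  expect_setequal(rec2$gene, names(oracle)[oracle >= 3])
  expect_identical(rec2$n_tumors,
                   as.integer(sort(oracle[oracle >= 3], decreasing = TRUE)))
})

test_that("segment calls use strict +-0.2 thresholds", {
  seg <- data.frame(sample_id = "T1", chrom = "chr1",
                    start = c(1, 11, 21), end = c(10, 20, 30),
                    seg_mean = c(0.2, -0.3, 0.5))
  calls <- call_segment_aberrations(seg)
  expect_identical(calls$call, c("neutral", "del", "amp"))
  expect_error(call_segment_aberrations(seg, amp_cut = -0.2, del_cut = 0.2),
               "exceed")
})

test_that("aberration index is the aberrant length fraction", {
  seg <- data.frame(sample_id = "T1", chrom = "chr1",
                    start = c(1, 11, 41), end = c(10, 40, 100),
                    seg_mean = c(0.5, 0.0, -0.5))  # lengths 10, 30, 60
  idx <- aberration_index(call_segment_aberrations(seg))
  expect_equal(unname(idx), 0.7)  # (10 + 60) / 100

  neutral <- data.frame(sample_id = "T2", chrom = "chr1",
                        start = 1, end = 100, seg_mean = 0.1)
  expect_equal(unname(aberration_index(call_segment_aberrations(neutral))), 0)

  sim <- simulate_cohorts(small_config(n = 25, seed = 31))
  ai <- aberration_index(call_segment_aberrations(sim$segments))
  expect_true(all(ai >= 0 & ai <= 1))
})

test_that("gene-level copy number follows the longest-overlap rule", {
  seg <- data.frame(sample_id = "T1", chrom = "chr1",
                    start = c(1, 1001), end = c(1000, 5000),
                    seg_mean = c(0.8, -0.6))
  genes <- data.frame(gene = c("IN_FIRST", "SPANNING"),
                      chrom = "chr1",
                      start = c(100, 901), end = c(200, 1900))
  cn <- gene_copy_number(seg, genes)
  # IN_FIRST fully inside segment 1; SPANNING overlaps 100 bp / 900 bp
  expect_equal(cn$seg_mean[cn$gene == "IN_FIRST"], 0.8)
  expect_equal(cn$seg_mean[cn$gene == "SPANNING"], -0.6)
  expect_identical(cn$call[cn$gene == "IN_FIRST"], "amp")

  # no overlap -> gene missing from the output
  far <- data.frame(gene = "FAR", chrom = "chr2", start = 1, end = 10)
  expect_identical(nrow(gene_copy_number(seg, far)), 0L)
})

test_that("gene-level copy number equals the brute-force interval oracle", {
  set.seed(32)
  genes <- data.frame(
    gene = sprintf("G%02d", 1:20),
    chrom = sample(paste0("chr", 1:3), 20, replace = TRUE),
    start = sample.int(9000, 20))
  genes$end <- genes$start + sample.int(800, 20)
  segments <- do.call(rbind, lapply(paste0("T", 1:10), function(sid) {
    do.call(rbind, lapply(paste0("chr", 1:3), function(ch) {
      # random non-overlapping tiling with gaps
      cuts <- sort(sample.int(10000, 10))
      starts <- cuts[seq(1, 9, by = 2)]
      ends <- cuts[seq(2, 10, by = 2)]
      data.frame(sample_id = sid, chrom = ch, start = starts, end = ends,
                 seg_mean = round(rnorm(5, 0, 0.4), 3))
    }))
  }))
  got <- gene_copy_number(segments, genes)
  want <- gene_cn_oracle(segments, genes)
  key <- function(d) d[order(d$sample_id, d$gene), c("sample_id", "gene",
                                                     "seg_mean")]
  expect_equal(key(got), key(want), ignore_attr = TRUE)
})

test_that("per-subtype aberration frequencies match hand counts", {
  seg <- data.frame(
    sample_id = c("T1", "T1", "T2", "T2"),
    chrom = "chr1",
    start = c(1, 11, 1, 11), end = c(10, 20, 10, 20),
    seg_mean = c(0.5, 0, 0.5, -0.5))
  calls <- call_segment_aberrations(seg)
  st <- c(T1 = "Basal-like", T2 = "Basal-like")
  freq <- subtype_cn_frequency(calls, st, bin_size = 10)
  b1 <- freq[freq$start == 1, ]
  b2 <- freq[freq$start == 11, ]
  expect_equal(b1$amp_freq, 1.0)   # both samples amp in bin 1
  expect_equal(b1$del_freq, 0.0)
  expect_equal(b2$amp_freq, 0.0)
  expect_equal(b2$del_freq, 0.5)   # only T2 deleted in bin 2
  expect_true(all(freq$amp_freq >= 0 & freq$amp_freq <= 1))

  expect_error(subtype_cn_frequency(calls, c(T1 = "Basal-like")),
               "unlabeled")
})

test_that("synthetic aberration load reproduces the subtype ordering", {
  sim <- simulate_cohorts(small_config(n = 120, seed = 33))
  ai <- aberration_index(call_segment_aberrations(sim$segments))
  st <- sim$truth$true_subtype[match(names(ai), sim$truth$sample_id)]
  med <- tapply(ai, st, median)
  expect_gt(med[["Basal-like"]], med[["Luminal B"]])
  expect_gt(med[["Luminal B"]], med[["HER2-enriched"]])
  expect_lt(abs(med[["HER2-enriched"]] - med[["Luminal A"]]), 0.12)
})
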