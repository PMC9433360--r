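# Shared fixtures: small simulation configs and a tiny deterministic
# expression matrix used across test files.

small_config <- function(n = 40, noise_sd = 0.5, seed = 1, ...) {
  sim_config(n_samples_per_cohort = n, noise_sd = noise_sd, seed = seed,
             n_genes = 120, ...)
}

# 4-gene x 6-sample matrix with known values (z-scored scale).
tiny_matrix <- function() {
  m <- matrix(c(1, 2, 3, 4, 5, 6,
                6, 5, 4, 3, 2, 1,
                0, 1, 0, 1, 0, 1,
                2, 2, 2, 2, 2, 2),
              nrow = 4, byrow = TRUE,
              dimnames = list(c("A", "B", "C", "D"), paste0("s", 1:6)))
  m
}

# Exhaustive interval-intersection oracle for gene-level copy number:
# per (sample, gene), scan all segments, return the seg_mean of the one
# with the longest overlap (first wins on ties, matching input order).
gene_cn_oracle <- function(segments, genes) {
  rows <- list()
  for (sid in unique(segments$sample_id)) {
    seg <- segments[segments$sample_id == sid, ]
    for (i in seq_len(nrow(genes))) {
      best_w <- 0
      best_sm <- NA_real_
      for (j in seq_len(nrow(seg))) {
        if (seg$chrom[j] != genes$chrom[i]) next
        w <- min(genes$end[i], seg$end[j]) - max(genes$start[i], seg$start[j]) + 1
        if (w > best_w) {
          best_w <- w
          best_sm <- seg$seg_mean[j]
        }
      }
      if (best_w > 0) {
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sid, gene = genes$gene[i], seg_mean = best_sm,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
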