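# The generator must be deterministic under a fixed seed, collapse to the
# centroids in the zero-noise limit, and reproduce the configured marginal
# structure (bimodal ESR1, subtype-dependent mutation and aberration rates).

test_that("config validation rejects malformed inputs", {
  expect_error(sim_config(subtype_proportions = c(0.5, 0.5, 0.1, 0.1)),
               "sum to 1")
  expect_error(sim_config(noise_sd = -1), "non-negative")
  expect_error(sim_config(dropout_genes = "NOT_A_GENE"), "subset")
  expect_error(sim_config(er_by_subtype = c(2, 0, 0, 0)), "probabilities")
  expect_error(sim_config(mutation_rates = list(TP53 = c(2, 0, 0, 0))),
               "\\[0, 1\\]")
  expect_error(sim_config(segment_params = c(-0.1, 0, 0, 0)), "fractions")
})

test_that("the same seed gives bit-identical output", {
  cfg <- small_config(n = 25, seed = 7)
  a <- simulate_cohorts(cfg)
  b <- simulate_cohorts(cfg)
  expect_identical(a, b)
  expect_false(identical(simulate_cohorts(small_config(n = 25, seed = 8)), a))
})

test_that("zero-noise samples equal their subtype centroid on the panel", {
  cfg <- small_config(n = 20, noise_sd = 0, seed = 3,
                      dropout_genes = character())
  sim <- simulate_cohorts(cfg)
  panel <- setdiff(rownames(sim$centroids), "ESR1")  # ESR1 is mode-driven
  for (i in seq_len(10)) {
    sid <- sim$truth$sample_id[i]
    st <- sim$truth$true_subtype[i]
    expect_equal(unname(sim$expr_a[panel, sid]),
                 unname(sim$centroids[panel, st]))
  }
  expect_identical(rownames(sim$expr_b), rownames(sim$expr_a))
})

test_that("cohort 2 lacks the dropout genes, cohort 1 has them", {
  sim <- simulate_cohorts(small_config(n = 15, seed = 2))
  dropped <- c("BIRC5", "CXXC5", "FOXC1", "KRT17", "MIA", "NAT1")
  expect_true(all(dropped %in% rownames(sim$expr_a)))
  expect_false(any(dropped %in% rownames(sim$expr_b)))
})

test_that("ESR1 is bimodal with well-separated modes and tracks ER truth", {
  cfg <- small_config(n = 300, seed = 5)
  sim <- simulate_cohorts(cfg)
  esr1 <- c(sim$expr_a["ESR1", ], sim$expr_b["ESR1", ])
  d <- density(esr1, bw = "nrd0", n = 512, cut = 3)
  n_max <- sum(diff(sign(diff(d$y))) < 0)
  expect_identical(n_max, 2L)
  # values separate cleanly at the mode midpoint (modes 4 sd apart)
  mid <- mean(cfg$esr1_modes)
  er <- sim$truth$true_er[match(names(esr1), sim$truth$sample_id)]
  expect_gt(mean((esr1 > mid) == (er == "pos")), 0.999)
})

test_that("er_by_subtype = 1 forces the high ESR1 mode", {
  cfg <- small_config(n = 60, seed = 6, er_by_subtype = c(0, 0, 1, 0))
  sim <- simulate_cohorts(cfg)
  luma <- sim$truth$sample_id[sim$truth$true_subtype == "Luminal A" &
                                sim$truth$cohort == 1]
  expect_true(all(sim$expr_a["ESR1", luma] > mean(cfg$esr1_modes)))
  expect_true(all(sim$truth$true_er[sim$truth$true_subtype == "Luminal A"] ==
                    "pos"))
})

test_that("per-gene sample means match the centroid mixture mean (CLT)", {
  cfg <- sim_config(n_samples_per_cohort = 1000, n_genes = 60, seed = 9)
  labels <- simulate_labels(cfg)
  labels <- labels[labels$cohort == 1, ]
  m <- simulate_expression(labels, synthetic_centroids(), cfg)
  check <- setdiff(c("CCNB1", "ERBB2", "PGR", "KRT5"), "ESR1")
  mix_mean <- synthetic_centroids()[check, ] %*% cfg$subtype_proportions
  for (g in check) {
    tol <- 3 * sd(m[g, ]) / sqrt(ncol(m))
    expect_lt(abs(mean(m[g, ]) - mix_mean[g, 1]), tol)
  }
})

test_that("unknown subtype label is an error", {
  cfg <- small_config(n = 5, seed = 1)
  labels <- simulate_labels(cfg)[1:3, ]
  labels$true_subtype[1] <- "Claudin-low"
  expect_error(simulate_expression(labels, synthetic_centroids(), cfg),
               "unknown subtype")
})

test_that("segments tile the toy genome without overlap", {
  sim <- simulate_cohorts(small_config(n = 10, seed = 4))
  seg <- sim$segments
  expect_true(all(seg$start <= seg$end))
  one <- seg[seg$sample_id == seg$sample_id[1], ]
  for (ch in unique(one$chrom)) {
    s <- one[one$chrom == ch, ]
    s <- s[order(s$start), ]
    expect_true(all(s$start[-1] == s$end[-nrow(s)] + 1))  # gap-free tiling
    expect_identical(s$start[1], 1)
    expect_identical(s$end[nrow(s)], 100e6)
  }
})

test_that("aberrant fraction 0 keeps all segment means inside [-0.2, 0.2]", {
  cfg <- small_config(n = 20, seed = 11, segment_params = c(0, 0, 0, 0))
  seg <- simulate_segments(simulate_labels(cfg), cfg)
  expect_true(all(abs(seg$seg_mean) <= 0.2))
})

test_that("configured aberration load orders the subtype means", {
  cfg <- sim_config(n_samples_per_cohort = 150, n_genes = 60, seed = 13,
                    segment_params = c(0.4, 0.1, 0.05, 0.3))
  labels <- simulate_labels(cfg)
  idx <- aberration_index(call_segment_aberrations(
    simulate_segments(labels, cfg)))
  by_st <- tapply(idx[labels$sample_id], labels$true_subtype, mean)
  expect_gt(by_st[["Basal-like"]], by_st[["Luminal B"]])
  expect_gt(by_st[["Luminal B"]], by_st[["HER2-enriched"]])
  expect_gt(by_st[["HER2-enriched"]], by_st[["Luminal A"]])
  # expectation targets the configured fraction
  expect_lt(abs(by_st[["Basal-like"]] - 0.4), 0.03)
})

test_that("mutation rates 1 and 0 behave deterministically", {
  cfg1 <- small_config(n = 30, seed = 14,
                       mutation_rates = list(TP53 = c(1, 0, 0, 0)))
  labels <- simulate_labels(cfg1)
  mut <- simulate_mutations(labels, cfg1)
  basal <- labels$sample_id[labels$true_subtype == "Basal-like"]
  expect_setequal(mut$sample_id[mut$gene == "TP53"], basal)
  expect_true(all(mut$consequence == "missense_variant"))

  cfg0 <- small_config(n = 30, seed = 14,
                       mutation_rates = list(TP53 = c(0, 0, 0, 0)))
  expect_identical(nrow(simulate_mutations(labels, cfg0)), 0L)
})

test_that("subtype-dependent TP53 rates are detectable by Fisher's test", {
  # power check: basal 0.5 vs luminal A 0.05, ~200 tumors
  reps <- 20
  hits <- 0
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_samples_per_cohort = 100, n_genes = 60,
                      seed = 100 + r,
                      mutation_rates = list(TP53 = c(0.5, 0.05, 0.05, 0.05)))
    labels <- simulate_labels(cfg)
    mut <- simulate_mutations(labels, cfg)
    is_basal <- labels$true_subtype == "Basal-like"
    mutated <- labels$sample_id %in% mut$sample_id[mut$gene == "TP53"]
    tab <- table(is_basal, mutated)
    p <- fisher_exact_rc(tab)$p
    if (p < 0.01) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("clinical labels are consistent with truth and valid categories", {
  sim <- simulate_cohorts(small_config(n = 80, seed = 15))
  cl <- sim$clinical
  expect_identical(cl$sample_id, sim$truth$sample_id)
  expect_true(all(cl$histology %in% c("Simple carcinoma", "Complex carcinoma",
                                      "Mixed tumor", "Benign",
                                      "Other histology")))
  expect_true(all(is.na(cl$grade[cl$histology == "Benign"])))
  expect_true(all(cl$lymph_node %in% c("Absent", "Present")))
})
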