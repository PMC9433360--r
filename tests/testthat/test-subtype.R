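# ER calling, centering variants, centroid correlation and assignment:
# exact toys, hand-computed correlations, and invariance properties.

test_that("bimodal cutoff lands at the density minimum near 0", {
  set.seed(10)
  x <- c(rnorm(250, -2, 0.3), rnorm(250, 2, 0.3))
  cut <- estimate_bimodal_cutoff(x)
  expect_lt(abs(cut$cutoff), 0.3)
  expect_gt(cut$cutoff, cut$modes[1])
  expect_lt(cut$cutoff, cut$modes[2])
})

test_that("unimodal input has no cutoff", {
  set.seed(11)
  expect_error(estimate_bimodal_cutoff(rnorm(500)), "no bimodal")
  expect_error(estimate_bimodal_cutoff(rnorm(10)), "20 finite")
})

test_that("ER call uses a strict boundary", {
  m <- matrix(c(-1, 0, 0.5), 1, dimnames = list("ESR1", paste0("s", 1:3)))
  er <- call_er_status(m, cutoff = 0)
  expect_identical(unname(er), c("neg", "neg", "pos"))  # 0 is not > 0
  expect_identical(unname(call_er_status(m, cutoff = -5)),
                   rep("pos", 3))
  expect_error(call_er_status(m, 0, esr1_gene = "PGR"), "not present")
})

test_that("ER-stratified centering zeroes each stratum", {
  m <- matrix(c(1, 3, 10, 12), 1,
              dimnames = list("G", paste0("s", 1:4)))
  er <- setNames(c("pos", "pos", "neg", "neg"), colnames(m))
  cen <- er_stratified_center(m, er)
  expect_equal(unname(cen[1, ]), c(-1, 1, -1, 1))

  # equal stratum means degenerate to plain centering
  m2 <- matrix(c(1, 3, 1, 3), 1, dimnames = list("G", paste0("s", 1:4)))
  expect_equal(er_stratified_center(m2, er), m2 - mean(m2),
               ignore_attr = TRUE)

  set.seed(12)
  r <- matrix(rnorm(300), 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:30)))
  err <- setNames(rep(c("pos", "neg"), 15), colnames(r))
  cr <- er_stratified_center(r, err)
  expect_lt(max(abs(rowMeans(cr[, err == "pos"]))), 1e-9)
  expect_lt(max(abs(rowMeans(cr[, err == "neg"]))), 1e-9)

  expect_error(er_stratified_center(r[, 1:3],
                                    setNames(c("pos", "pos", "neg"),
                                             colnames(r)[1:3])),
               "at least two samples")
})

test_that("balanced centering subtracts the average of stratum means", {
  m <- matrix(c(1, 3, 10, 12), 1, dimnames = list("G", paste0("s", 1:4)))
  er <- setNames(c("pos", "pos", "neg", "neg"), colnames(m))
  cen <- er_balanced_center(m, er)
  expect_equal(unname(cen[1, ]), c(1, 3, 10, 12) - (2 + 11) / 2)
  # one common offset: between-sample differences are untouched
  expect_equal(diff(cen[1, ]), diff(m[1, ]))
})

test_that("centroid correlations hit exact values on constructed profiles", {
  ct <- synthetic_centroids()
  genes <- rownames(ct)
  m <- cbind(pos_basal = ct[, "Basal-like"], neg_basal = -ct[, "Basal-like"])
  r <- correlate_to_centroids(m, ct)
  expect_equal(r["pos_basal", "Basal-like"], 1.0)
  expect_equal(r["neg_basal", "Basal-like"], -1.0)

  # 3-gene toy against a single known Pearson value
  toy_ct <- matrix(c(1, 2, 4), 3, 4,
                   dimnames = list(c("a", "b", "c"), pam50_subtypes()))
  toy <- matrix(c(1, 2, 3), 3, dimnames = list(c("a", "b", "c"), "s1"))
  r2 <- correlate_to_centroids(toy, toy_ct)
  expect_equal(unname(r2["s1", "Basal-like"]), 0.9819805, tolerance = 1e-6)

  expect_error(correlate_to_centroids(toy[1:2, , drop = FALSE], toy_ct),
               "at least 3 genes")
  flat <- matrix(1, 3, 1, dimnames = list(c("a", "b", "c"), "sflat"))
  rf <- correlate_to_centroids(flat, toy_ct)
  expect_true(all(is.na(rf["sflat", ])))
  expect_identical(attr(rf, "flagged"), "sflat")
})

test_that("genes absent from the matrix are dropped from the centroids", {
  ct <- synthetic_centroids()
  keep <- setdiff(rownames(ct), c("BIRC5", "CXXC5", "FOXC1",
                                  "KRT17", "MIA", "NAT1"))
  m <- cbind(s1 = ct[keep, "Luminal A"])
  r <- correlate_to_centroids(m, ct)
  expect_identical(length(attr(r, "genes_used")), 44L)
  expect_equal(r["s1", "Luminal A"], 1.0)
})

test_that("assignment takes the argmax with canonical tie-breaking", {
  r <- rbind(s1 = c(0.45, 0.25, 0.10, 0.05),
             s2 = c(0.30, 0.30, 0.10, 0.05),
             s3 = c(0.10, 0.20, 0.80, 0.40))
  colnames(r) <- pam50_subtypes()
  a <- assign_subtype(r)
  expect_identical(a$subtype, c("Basal-like", "Basal-like", "Luminal A"))
  expect_equal(a$margin, c(0.20, 0, 0.40))
  expect_identical(a$tie_flag, c(FALSE, TRUE, FALSE))

  r2 <- rbind(r, s4 = c(NaN, 0.2, 0.1, 0))
  colnames(r2) <- pam50_subtypes()
  expect_message(a2 <- assign_subtype(r2), "excluded")
  expect_identical(attr(a2, "excluded"), "s4")
  expect_identical(nrow(a2), 3L)
})

test_that("correlations are invariant to a per-sample constant shift", {
  sim <- simulate_cohorts(small_config(n = 10, seed = 41))
  m <- sim$expr_a[rownames(sim$centroids), ]
  r1 <- correlate_to_centroids(m, sim$centroids)
  shifted <- m
  shifted[, 3] <- shifted[, 3] + 7.5
  r2 <- correlate_to_centroids(shifted, sim$centroids)
  expect_equal(r1, r2)
})

test_that("relabeling centroid columns permutes assignments consistently", {
  sim <- simulate_cohorts(small_config(n = 40, seed = 42))
  run <- run_synthetic_study(sim)
  # swap the meaning of the basal-like and luminal A centroids
  ct2 <- sim$centroids
  ct2[, c("Basal-like", "Luminal A")] <- ct2[, c("Luminal A", "Basal-like")]
  fit2 <- pam50(run$merged, ct2, er_cutoff = run$fit$er_cutoff)
  swap <- c("Basal-like" = "Luminal A", "Luminal A" = "Basal-like",
            "HER2-enriched" = "HER2-enriched", "Luminal B" = "Luminal B")
  expect_identical(unname(swap[run$calls$subtype]), fit2$calls$subtype)
})

test_that("identical panels agree perfectly; a 44-gene panel is faithful", {
  sim <- simulate_cohorts(small_config(n = 80, seed = 43,
                                       dropout_genes = character()))
  run <- run_synthetic_study(sim)
  er <- setNames(run$calls$er_status, run$calls$sample_id)
  cen <- er_balanced_center(run$merged, er)
  panel <- rownames(sim$centroids)
  expect_equal(unname(panel_reduction_check(cen, sim$centroids,
                                            panel, panel)),
               rep(1.0, 4))
  set.seed(7)
  reduced <- setdiff(panel, sample(setdiff(panel, "ESR1"), 6))
  agree <- panel_reduction_check(cen, sim$centroids, panel, reduced)
  expect_true(all(agree > 0.9))
  # sanity direction: tiny disjoint panels from different centroid blocks
  # cannot agree perfectly
  tiny <- panel_reduction_check(cen, sim$centroids,
                                c("ANLN", "CCNB1", "ESR1"),
                                c("ERBB2", "GRB7", "KRT5"))
  expect_true(any(abs(tiny) < 0.9))
})

test_that("Cohen's kappa concordance matches hand values", {
  expect_equal(concordance_kappa(c(a = "x", b = "y"), c(a = "x", b = "y")), 1.0)
  # agreement table [[20,5],[10,15]]: p_o = 0.7, p_e = 0.5
  a <- rep(c("A", "A", "B", "B"), c(20, 5, 10, 15))
  b <- rep(c("A", "B", "A", "B"), c(20, 5, 10, 15))
  expect_equal(concordance_kappa(a, b), 0.4)
  set.seed(13)
  ra <- sample(letters[1:4], 4000, replace = TRUE)
  rb <- sample(letters[1:4], 4000, replace = TRUE)
  expect_lt(abs(concordance_kappa(ra, rb)), 0.05)
  expect_error(concordance_kappa(c(x = "a"), c(y = "b")), "in common")
})
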