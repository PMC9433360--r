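# Synthetic two-cohort generator. Emulates the statistical structure the
# subtyping analysis assumes -- four subtype centroids with Gaussian noise, a
# bimodal ESR1 gene, panel genes missing from one cohort, clinical labels
# with subtype-dependent frequencies, subtype-dependent mutation rates and
# segment tables with subtype-dependent aberration load -- with full ground
# truth, so every downstream stage is testable without accession downloads.

#' Classifier gene panel
#'
#' The 50-gene intrinsic-subtype classifier panel (standard human symbols).
#' @return Character vector of 50 gene symbols.
#' @export
pam50_panel <- function() {
  names(panel_blocks())
}

# Block structure of the panel used to build synthetic centroids:
# P = proliferation, L = luminal/hormone-receptor, E = ERBB2 amplicon,
# B = basal keratins and associated genes. The 10-gene proliferation
# signature of signature_score() is a subset of block P.
panel_blocks <- function() {
  c(ANLN = "P", BIRC5 = "P", CCNB1 = "P", CCNE1 = "P", CDC20 = "P",
    CDC6 = "P", CENPF = "P", CEP55 = "P", EXO1 = "P", KIF2C = "P",
    MELK = "P", MKI67 = "P", MYBL2 = "P", NDC80 = "P", NUF2 = "P",
    ORC6 = "P", PTTG1 = "P", RRM2 = "P", TYMS = "P", UBE2C = "P",
    UBE2T = "P",
    BAG1 = "L", BCL2 = "L", BLVRA = "L", ESR1 = "L", FOXA1 = "L",
    GPR160 = "L", MAPT = "L", MDM2 = "L", MLPH = "L", NAT1 = "L",
    PGR = "L", SLC39A6 = "L", TMEM45B = "L",
    ERBB2 = "E", FGFR4 = "E", GRB7 = "E",
    ACTR3B = "B", CDH3 = "B", CXXC5 = "B", EGFR = "B", FOXC1 = "B",
    KRT14 = "B", KRT17 = "B", KRT5 = "B", MIA = "B", MMP11 = "B",
    MYC = "B", PHGDH = "B", SFRP1 = "B")
}

#' Synthetic subtype centroids
#'
#' Block-structured reference profiles for the four intrinsic subtypes over
#' the classifier panel: the proliferation block is high in basal-like and
#' luminal B, the luminal block high in luminal A and B, the ERBB2 block
#' high in HER2-enriched, and the basal block high in basal-like. The
#' HER2-enriched and luminal B centroids are deliberately less distinct
#' (intermediate block values), mirroring the weaker separation those
#' subtypes show in real cohorts. Basal-like and luminal A are strongly
#' anticorrelated (r ~ -0.97).
#'
#' @return 50 x 4 numeric matrix, genes by subtype ([pam50_subtypes()]).
#' @export
#' @examples
#' round(cor(synthetic_centroids()), 2)
synthetic_centroids <- function() {
  blocks <- panel_blocks()
  vals <- cbind(
    "Basal-like"    = c(P =  1.0, L = -1.0, E = -0.5, B =  1.0),
    "HER2-enriched" = c(P =  0.3, L = -0.3, E =  1.5, B =  0.0),
    "Luminal A"     = c(P = -1.0, L =  1.0, E = -0.3, B = -0.8),
    "Luminal B"     = c(P =  0.8, L =  0.6, E =  0.3, B = -0.8))
  centroids <- vals[blocks, , drop = FALSE]
  rownames(centroids) <- names(blocks)
  centroids
}

# Subtype-conditional clinical label frequencies, derived from the printed
# cross-tabulations of the reference canine cohort (cmgt_clinical_tables()).
clinical_profile <- function() {
  tabs <- cmgt_clinical_tables()
  lapply(tabs, function(tb) sweep(tb, 2, colSums(tb), "/"))
}

#' Configure a synthetic two-cohort simulation
#'
#' Collects and validates every tunable of the generator. Defaults are the
#' study conditions: subtype proportions equal to the canine cohort's
#' observed distribution, ~75% ER-positive tumors overall with partially
#' ER-positive basal-like tumors, within-subtype noise s.d. 0.5, well
#' separated ESR1 modes at -2/+2 (s.d. 0.5), PIK3CA mutations enriched in
#' luminal and TP53 in basal-like tumors, and aberrant-genome fractions
#' ordered basal > luminal B > HER2 ~ luminal A.
#'
#' @param n_samples_per_cohort Samples per cohort (positive integer).
#' @param subtype_proportions Length-4 probability vector over
#'   [pam50_subtypes()]; must sum to 1 within 1e-9.
#' @param n_genes Total genes per cohort (>= panel size); non-panel genes
#'   are standard-normal noise.
#' @param panel_genes Classifier panel symbols (must match the centroids).
#' @param dropout_genes Panel genes absent from cohort 2 (subset of
#'   `panel_genes`); default: the six panel genes missing from the canine
#'   RNA-seq data (BIRC5, CXXC5, FOXC1, KRT17, MIA, NAT1).
#' @param noise_sd Within-subtype expression s.d. around the centroid
#'   (>= 0; 0 gives the exact zero-noise limit).
#' @param esr1_modes Length-2 numeric, low/high ESR1 mode locations.
#' @param mode_sd S.d. of each ESR1 mode (> 0).
#' @param er_by_subtype P(ER+ | subtype), length 4, values in [0, 1].
#' @param mutation_rates Named list, gene -> length-4 per-subtype Bernoulli
#'   mutation rate in [0, 1].
#' @param segment_params Length-4 expected aberrant genome fraction per
#'   subtype, in [0, 1].
#' @param seed Integer seed; the same seed gives bit-identical output.
#' @return Validated configuration object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_samples_per_cohort = 50, seed = 7)
#' sim <- simulate_cohorts(cfg)
#' table(sim$truth$true_subtype)
sim_config <- function(n_samples_per_cohort = 400,
                       subtype_proportions = c(0.268, 0.089, 0.586, 0.057),
                       n_genes = 500,
                       panel_genes = pam50_panel(),
                       dropout_genes = c("BIRC5", "CXXC5", "FOXC1",
                                         "KRT17", "MIA", "NAT1"),
                       noise_sd = 0.5,
                       esr1_modes = c(low = -2, high = 2),
                       mode_sd = 0.5,
                       er_by_subtype = c(0.35, 0.30, 0.95, 0.90),
                       mutation_rates = list(
                         PIK3CA = c(0.05, 0.10, 0.35, 0.30),
                         TP53 = c(0.50, 0.10, 0.03, 0.20)),
                       segment_params = c(0.40, 0.10, 0.05, 0.30),
                       seed = 1L) {
  st <- pam50_subtypes()
  .assert(length(n_samples_per_cohort) == 1 && n_samples_per_cohort >= 1,
          "n_samples_per_cohort must be a positive integer")
  .assert(length(subtype_proportions) == 4 && all(subtype_proportions >= 0),
          "subtype_proportions must be 4 non-negative values")
  .assert(abs(sum(subtype_proportions) - 1) < 1e-9,
          "subtype_proportions must sum to 1 (within 1e-9)")
  .assert(length(noise_sd) == 1 && is.finite(noise_sd) && noise_sd >= 0,
          "noise_sd must be a non-negative real")
  .assert(length(mode_sd) == 1 && mode_sd > 0, "mode_sd must be positive")
  .assert(length(esr1_modes) == 2 && esr1_modes[1] < esr1_modes[2],
          "esr1_modes must be two ordered values (low < high)")
  .assert(all(dropout_genes %in% panel_genes),
          "dropout_genes must be a subset of panel_genes")
  .assert(n_genes >= length(panel_genes),
          "n_genes must be at least the panel size")
  .assert(length(er_by_subtype) == 4 &&
            all(er_by_subtype >= 0 & er_by_subtype <= 1),
          "er_by_subtype must be 4 probabilities in [0, 1]")
  for (g in names(mutation_rates)) {
    r <- mutation_rates[[g]]
    .assert(length(r) == 4 && all(r >= 0 & r <= 1),
            sprintf("mutation rate for %s must be 4 values in [0, 1]", g))
  }
  .assert(length(segment_params) == 4 &&
            all(segment_params >= 0 & segment_params <= 1),
          "segment_params must be 4 fractions in [0, 1]")
  names(subtype_proportions) <- st
  names(er_by_subtype) <- st
  names(segment_params) <- st
  mutation_rates <- lapply(mutation_rates, function(r) {
    names(r) <- st
    r
  })
  structure(list(
    n_samples_per_cohort = as.integer(n_samples_per_cohort),
    subtype_proportions = subtype_proportions,
    n_genes = as.integer(n_genes),
    panel_genes = panel_genes,
    dropout_genes = dropout_genes,
    noise_sd = noise_sd,
    esr1_modes = esr1_modes,
    mode_sd = mode_sd,
    er_by_subtype = er_by_subtype,
    mutation_rates = mutation_rates,
    segment_params = segment_params,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic two-cohort simulation configuration\n")
  cat(sprintf("  %d samples/cohort, %d genes (%d panel, %d dropped in cohort 2)\n",
              x$n_samples_per_cohort, x$n_genes, length(x$panel_genes),
              length(x$dropout_genes)))
  cat(sprintf("  noise sd %.3g; ESR1 modes %.3g / %.3g (sd %.3g); seed %d\n",
              x$noise_sd, x$esr1_modes[1], x$esr1_modes[2], x$mode_sd, x$seed))
  cat("  subtype proportions:",
      paste(sprintf("%s %.3f", names(x$subtype_proportions),
                    x$subtype_proportions), collapse = ", "), "\n")
  invisible(x)
}

# Fixed RNG offsets: each stage draws from its own stream derived from the
# config seed, so stages can be rerun independently with identical output.
.seed_offsets <- c(labels = 0L, expression = 1L, segments = 2L,
                   mutations = 3L, clinical = 4L)

stage_seed <- function(config, stage) {
  config$seed + .seed_offsets[[stage]]
}

#' Draw ground-truth sample labels
#'
#' @param config A [sim_config()] object.
#' @return Data frame (one row per sample): `sample_id`, `true_subtype`,
#'   `true_er` (`"pos"`/`"neg"`), `cohort` (`1` or `2`).
#' @export
simulate_labels <- function(config) {
  n <- config$n_samples_per_cohort
  st <- pam50_subtypes()
  with_seed(stage_seed(config, "labels"), {
    subtype <- sample(st, 2L * n, replace = TRUE,
                      prob = config$subtype_proportions)
    er <- ifelse(stats::runif(2L * n) < config$er_by_subtype[subtype],
                 "pos", "neg")
    data.frame(
      sample_id = sprintf("S%d_%04d", rep(1:2, each = n), c(seq_len(n), seq_len(n))),
      true_subtype = subtype,
      true_er = er,
      cohort = rep(1:2, each = n),
      stringsAsFactors = FALSE)
  })
}

#' Simulate an expression matrix from truth labels
#'
#' Panel genes are drawn as centroid value + N(0, noise_sd^2); non-panel
#' filler genes are N(0, 1); ESR1 is overridden with a draw from the mode
#' matching the sample's true ER status, giving a bimodal marginal.
#'
#' @param labels Truth table from [simulate_labels()] (any subset of rows).
#' @param centroids Gene x subtype centroid matrix (default
#'   [synthetic_centroids()]); every label's subtype must be a column.
#' @param config A [sim_config()] object.
#' @return Gene x sample expression matrix (log-like scale) with the
#'   cohort tag of the labels' first cohort.
#' @export
simulate_expression <- function(labels, centroids = synthetic_centroids(),
                                config) {
  .assert(all(labels$true_subtype %in% colnames(centroids)),
          "unknown subtype label: ",
          paste(setdiff(labels$true_subtype, colnames(centroids)),
                collapse = ", "))
  panel <- intersect(rownames(centroids), config$panel_genes)
  n_fill <- config$n_genes - length(panel)
  filler <- if (n_fill > 0) sprintf("FILLER%04d", seq_len(n_fill)) else character()
  n <- nrow(labels)
  # separate stream per cohort so the two cohorts' noise is independent
  seed <- stage_seed(config, "expression") + 1009L * (labels$cohort[1] - 1L)
  with_seed(seed, {
    mu <- centroids[panel, labels$true_subtype, drop = FALSE]
    vals <- mu + stats::rnorm(length(mu), 0, config$noise_sd)
    fill <- matrix(stats::rnorm(n_fill * n), nrow = n_fill,
                   dimnames = list(filler, labels$sample_id))
    m <- rbind(vals, fill)
    colnames(m) <- labels$sample_id
    if ("ESR1" %in% rownames(m)) {
      mode <- ifelse(labels$true_er == "pos",
                     config$esr1_modes[2], config$esr1_modes[1])
      m["ESR1", ] <- stats::rnorm(n, mode, config$mode_sd)
    }
    expr_matrix(m, cohort = paste0("cohort", labels$cohort[1]), scale = "log2")
  })
}

#' Simulate a segmented copy-number table
#'
#' Segments tile a fixed toy genome (5 chromosomes x 100 Mb, 5-Mb segments,
#' 1-based inclusive). Each segment is aberrant with the subtype's
#' configured probability; aberrant segment means are drawn uniformly from
#' +-(0.25, 0.8) (beyond the +-0.2 call threshold), neutral means from
#' (-0.15, 0.15), so the expected aberrant genome fraction equals the
#' configured fraction.
#'
#' @inheritParams simulate_expression
#' @return SEG-style data frame: `sample_id`, `chrom`, `start`, `end`,
#'   `seg_mean`.
#' @export
simulate_segments <- function(labels, config) {
  frac <- config$segment_params
  .assert(all(labels$true_subtype %in% names(frac)),
          "segment_params missing for some subtype")
  genome <- toy_genome()
  n_seg <- nrow(genome)
  with_seed(stage_seed(config, "segments"), {
    out <- lapply(seq_len(nrow(labels)), function(i) {
      f <- frac[[labels$true_subtype[i]]]
      ab <- stats::runif(n_seg) < f
      sm <- stats::runif(n_seg, -0.15, 0.15)
      n_ab <- sum(ab)
      if (n_ab > 0) {
        sm[ab] <- sample(c(-1, 1), n_ab, replace = TRUE) *
          stats::runif(n_ab, 0.25, 0.8)
      }
      data.frame(sample_id = labels$sample_id[i], genome,
                 seg_mean = sm, stringsAsFactors = FALSE)
    })
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}

#' Toy genome tiling used by the segment simulator
#'
#' @param n_chrom,chrom_length,seg_length Chromosome count, chromosome
#'   length and segment length in bp.
#' @return Data frame of `chrom`, `start`, `end` tiling the toy genome with
#'   non-overlapping 1-based inclusive segments.
#' @export
toy_genome <- function(n_chrom = 5, chrom_length = 100e6, seg_length = 5e6) {
  per <- chrom_length / seg_length
  .assert(per == round(per), "chrom_length must be a multiple of seg_length")
  starts <- seq(1, chrom_length, by = seg_length)
  data.frame(
    chrom = rep(paste0("chr", seq_len(n_chrom)), each = per),
    start = rep(starts, n_chrom),
    end = rep(starts + seg_length - 1, n_chrom),
    stringsAsFactors = FALSE)
}

#' Simulate a somatic mutation table
#'
#' One Bernoulli draw per (sample, gene) at the gene's subtype-specific
#' rate; emitted rows carry consequence class `"missense_variant"`.
#'
#' @inheritParams simulate_expression
#' @return Data frame `sample_id`, `gene`, `consequence` (possibly
#'   zero rows).
#' @export
simulate_mutations <- function(labels, config) {
  with_seed(stage_seed(config, "mutations"), {
    rows <- lapply(names(config$mutation_rates), function(g) {
      p <- config$mutation_rates[[g]][labels$true_subtype]
      hit <- labels$sample_id[stats::runif(nrow(labels)) < p]
      data.frame(sample_id = hit,
                 gene = rep(g, length(hit)),
                 consequence = rep("missense_variant", length(hit)),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out) || nrow(out) == 0) {
      return(data.frame(sample_id = character(), gene = character(),
                        consequence = character(), stringsAsFactors = FALSE))
    }
    out <- out[order(out$sample_id, out$gene), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Simulate a clinical annotation table
#'
#' Histology, grade, lymph-node status and neuter status are drawn per
#' sample from subtype-conditional frequencies taken from the reference
#' canine cohort's printed cross-tabulations ([cmgt_clinical_tables()]).
#' Benign tumors get grade `NA` (grade applies to malignant tumors only).
#'
#' @inheritParams simulate_expression
#' @return Data frame `sample_id`, `histology`, `grade`, `lymph_node`,
#'   `neuter`.
#' @export
simulate_clinical <- function(labels, config) {
  prof <- clinical_profile()
  draw <- function(tb, subtype) {
    vapply(subtype, function(s) {
      sample(rownames(tb), 1L, prob = tb[, s])
    }, character(1))
  }
  with_seed(stage_seed(config, "clinical"), {
    histology <- draw(prof$histology, labels$true_subtype)
    grade <- draw(prof$grade, labels$true_subtype)
    grade[histology == "Benign"] <- NA_character_
    neuter <- draw(prof$neuter, labels$true_subtype)
    neuter[neuter == "NA"] <- NA_character_  # unknown status
    data.frame(
      sample_id = labels$sample_id,
      histology = histology,
      grade = grade,
      lymph_node = draw(prof$lymph_node, labels$true_subtype),
      neuter = neuter,
      stringsAsFactors = FALSE)
  })
}

#' Generate a complete synthetic two-cohort study
#'
#' Runs every generator stage under one configuration: truth labels for two
#' cohorts, an expression matrix per cohort (cohort 2 lacking the dropout
#' genes), clinical annotation, a segmented copy-number table and a somatic
#' mutation table, all consistent with the truth labels. Rerunning with the
#' same configuration is bit-identical.
#'
#' @param config A [sim_config()] object.
#' @return List with elements `expr_a`, `expr_b` (gene x sample matrices),
#'   `clinical`, `segments`, `mutations`, `truth` (data frames) and
#'   `centroids` (the generating centroid matrix).
#' @export
#' @examples
#' sim <- simulate_cohorts(sim_config(n_samples_per_cohort = 30, seed = 1))
#' dim(sim$expr_a); dim(sim$expr_b)
simulate_cohorts <- function(config) {
  .assert(inherits(config, "sim_config"), "config must come from sim_config()")
  centroids <- synthetic_centroids()
  centroids <- centroids[intersect(rownames(centroids), config$panel_genes), ,
                         drop = FALSE]
  truth <- simulate_labels(config)
  expr_a <- simulate_expression(truth[truth$cohort == 1, ], centroids, config)
  expr_b <- simulate_expression(truth[truth$cohort == 2, ], centroids, config)
  keep <- setdiff(rownames(expr_b), config$dropout_genes)
  expr_b <- carry_meta(expr_b[keep, , drop = FALSE], expr_b)
  list(
    expr_a = expr_a,
    expr_b = expr_b,
    clinical = simulate_clinical(truth, config),
    segments = simulate_segments(truth, config),
    mutations = simulate_mutations(truth, config),
    truth = truth,
    centroids = centroids)
}
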