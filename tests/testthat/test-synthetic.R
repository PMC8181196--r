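test_that("generators are deterministic under a fixed seed", {
  a <- small_cohort(seed = 5L)
  b <- small_cohort(seed = 5L)
  expect_identical(a$lnc$values, b$lnc$values)
  expect_identical(a$mrna$values, b$mrna$values)
  expect_identical(a$labels, b$labels)

  s1 <- apply_batch_shift(a$lnc, 2, seed = 9L)
  s2 <- apply_batch_shift(a$lnc, 2, seed = 9L)
  expect_identical(s1$values, s2$values)

  sc <- survival_config(baseline_hazard_per_subtype = rep(0.05, 3),
                        treatment_hazard_ratio_per_subtype = rep(0.5, 3))
  r1 <- generate_survival(a$labels, "untreated", sc, seed = 3L)
  r2 <- generate_survival(a$labels, "untreated", sc, seed = 3L)
  expect_identical(r1, r2)

  dc <- drug_panel_config(n_cell_lines = 10)
  p <- rep(0.5, 10)
  expect_identical(generate_drug_panel(p, dc, 4L),
                   generate_drug_panel(p, dc, 4L))
})

test_that("cohort config enforces its invariants", {
  expect_error(cohort_config(subtype_proportions = c(0.5, 0.4),
                             k_subtypes = 2), "sum to 1")
  expect_error(cohort_config(subtype_proportions = rep(0.25, 4)),
               "length k_subtypes")
  expect_error(cohort_config(noise_sd = 0), "noise_sd")
  expect_error(cohort_config(n_lnc_genes = 100,
                             n_marker_genes_per_subtype = 50),
               "exceeds the gene count")
  # marker blocks are disjoint between subtypes
  co <- small_cohort()
  all_markers <- unlist(co$marker_genes$lnc)
  expect_identical(anyDuplicated(all_markers), 0L)
})

test_that("zero effect size gives exchangeable genes across subtypes", {
  co <- small_cohort(seed = 2L, effect = 0, n = 120L)
  g1 <- co$mrna$values[, co$labels == 1, drop = FALSE]
  g2 <- co$mrna$values[, co$labels == 2, drop = FALSE]
  diffs <- rowMeans(g1) - rowMeans(g2)
  se <- 0.5 * sqrt(1 / ncol(g1) + 1 / ncol(g2))
  expect_lt(abs(mean(diffs)), 3 * se / sqrt(length(diffs)) * 5)
  expect_lt(mean(abs(diffs) > 3 * se), 0.02)  # ~0.27% expected
})

test_that("label counts fall in binomial 99% bounds at uniform k=6", {
  co <- generate_training_cohort(cohort_config(
    n_samples = 300, n_lnc_genes = 60, n_mrna_genes = 60,
    k_subtypes = 6, n_marker_genes_per_subtype = 10, seed = 31L))
  bounds <- qbinom(c(0.005, 0.995), 300, 1 / 6)
  counts <- tabulate(co$labels, 6)
  expect_true(all(counts >= bounds[1] & counts <= bounds[2]))
})

test_that("marker shift matches the configured effect size", {
  co <- small_cohort(seed = 8L, k = 2L, effect = 5, noise = 0.5, n = 80L)
  mk <- co$mrna$values[co$marker_genes$mrna[[1]], , drop = FALSE]
  n1 <- sum(co$labels == 1); n2 <- sum(co$labels == 2)
  d <- rowMeans(mk[, co$labels == 1]) - rowMeans(mk[, co$labels == 2])
  se <- 0.5 * sqrt(1 / n1 + 1 / n2)
  expect_true(all(abs(d - 5) < 3 * se + 1e-9 | abs(d - 5) < 4 * se))
  expect_equal(mean(d), 5, tolerance = 3 * se / sqrt(length(d)) * 2)
})

test_that("markers co-vary within their subtype more than across", {
  co <- small_cohort(seed = 12L, effect = 2, noise = 0.5)
  cors <- cor(t(co$lnc$values[unlist(co$marker_genes$lnc), ]))
  m <- length(co$marker_genes$lnc[[1]])
  same <- outer(rep(1:3, each = m), rep(1:3, each = m), "==")
  diag(same) <- NA
  expect_gt(mean(cors[same & !is.na(same)]),
            mean(cors[!same], na.rm = TRUE))
})

test_that("batch shift is additive per gene and vanishes at sd 0", {
  co <- small_cohort(seed = 3L)
  expect_identical(apply_batch_shift(co$lnc, 0, seed = 1L)$values,
                   co$lnc$values)
  big <- em(matrix(rnorm(1000 * 3), 1000, 3))
  shifted <- apply_batch_shift(big, 2, seed = 6L)
  offsets <- shifted$values[, 1] - big$values[, 1]
  # same offset applied to every sample
  expect_equal(shifted$values[, 2] - big$values[, 2], offsets)
  # chi-square 99% interval for the SD of 1000 N(0, 2^2) draws
  ci <- 2 * sqrt(qchisq(c(0.005, 0.995), 999) / 999)
  expect_gt(sd(offsets), ci[1])
  expect_lt(sd(offsets), ci[2])
  expect_error(apply_batch_shift(big, -1, 1L), ">= 0")
})

test_that("survival records follow the competing-exponential model", {
  labels <- rep(1L, 1000); names(labels) <- sprintf("S%04d", 1:1000)
  sc <- survival_config(baseline_hazard_per_subtype = 0.1,
                        treatment_hazard_ratio_per_subtype = 1,
                        censoring_rate = 0, max_followup = 1e6)
  rec <- generate_survival(labels, "untreated", sc, seed = 21L)
  expect_true(all(rec$event == 1))
  expect_equal(mean(rec$time), 10, tolerance = 3 * 10 / sqrt(1000))

  # event fraction = h / (h + c) within 3 SE at n = 1000
  sc2 <- survival_config(baseline_hazard_per_subtype = 0.1,
                         treatment_hazard_ratio_per_subtype = 1,
                         censoring_rate = 0.05, max_followup = 1e6)
  rec2 <- generate_survival(labels, "untreated", sc2, seed = 22L)
  frac <- 0.1 / 0.15
  expect_equal(mean(rec2$event), frac,
               tolerance = 3 * sqrt(frac * (1 - frac) / 1000))

  # near-infinite censoring rate censors everything almost immediately
  sc3 <- survival_config(baseline_hazard_per_subtype = 0.1,
                         treatment_hazard_ratio_per_subtype = 1,
                         censoring_rate = 1e6, max_followup = 100)
  rec3 <- generate_survival(labels, "untreated", sc3, seed = 23L)
  expect_true(all(rec3$event == 0))
  expect_lt(max(rec3$time), 0.01)
  expect_error(generate_survival(c(a = 9L), "untreated", sc3, 1L),
               "unknown label")
})

test_that("drug panel couples AUC to probability as configured", {
  set.seed(99)
  p <- runif(40)
  names(p) <- sprintf("CL%03d", 1:40)
  strong <- drug_panel_config(coupled_drug_indices = 1,
                              coupling_slope = -10, auc_noise_sd = 0.1)
  auc <- generate_drug_panel(p, strong, seed = 17L)
  expect_lt(cor(p, auc[1, ], method = "spearman"), -0.9)

  null <- drug_panel_config(coupled_drug_indices = integer(0))
  auc0 <- generate_drug_panel(p, null, seed = 18L)
  rhos <- apply(auc0, 1, function(a) cor(p, a, method = "spearman"))
  expect_lt(abs(mean(rhos)), 0.15)

  # degenerate constant probabilities still produce a valid panel
  flat <- generate_drug_panel(rep(0.3, 40), strong, seed = 19L)
  expect_identical(dim(flat), c(20L, 40L))
  expect_error(generate_drug_panel(rep(2, 40), strong, 1L), "\\[0, 1\\]")
})
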