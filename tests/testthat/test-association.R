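test_that("cross-tabulation counts shared samples per class pair", {
  a <- setNames(c(1, 1, 2, 2, 3), paste0("s", 1:5))
  b <- setNames(c("x", "y", "y", "y", "x"), paste0("s", 1:5))
  ct <- cross_tabulate(a, b)
  expect_equal(unclass(ct)[, ],
               matrix(c(1, 0, 1, 1, 2, 0), 3, 2,
                      dimnames = list(c("1", "2", "3"), c("x", "y"))),
               ignore_attr = TRUE)
  expect_identical(attr(ct, "n_common"), 5L)
  expect_equal(sum(ct), 5)
  # identical labelings give a diagonal matrix
  d <- cross_tabulate(a, a)
  expect_true(all(d[upper.tri(d)] == 0) && all(d[lower.tri(d)] == 0))
  # only the intersection of sample IDs counts
  ct2 <- cross_tabulate(a, b[1:3])
  expect_identical(attr(ct2, "n_common"), 3L)
  expect_error(cross_tabulate(a, setNames(1, "zz")), "empty")
})

test_that("Spearman rho matches cor.test on exact and tied data", {
  p <- setNames(seq(0.1, 0.9, length.out = 5), paste0("c", 1:5))
  auc <- matrix(c(9, 7, 5, 3, 1), 1, 5,
                dimnames = list("d1", names(p)))
  scr <- spearman_screen(p, auc)
  expect_equal(scr$rho, -1)
  set.seed(15)
  for (n in c(5, 8, 12, 25)) {
    x <- setNames(runif(n), paste0("c", 1:n))
    y <- matrix(round(rnorm(n), 1), 1, n, dimnames = list("d", names(x)))
    scr <- spearman_screen(x, y)
    ref <- suppressWarnings(cor.test(x, y[1, ], method = "spearman"))
    expect_equal(scr$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_identical(scr$n, as.integer(n))
  }
})

test_that("exact permutation p agrees with enumeration on a 5-pair toy", {
  x <- setNames(c(0.1, 0.3, 0.5, 0.7, 0.9), paste0("c", 1:5))
  y <- matrix(c(4, 2, 5, 1, 3), 1, 5, dimnames = list("d", names(x)))
  scr <- spearman_screen(x, y)
  # brute force over all 120 orderings
  perms <- lncsubtype:::all_permutations(5)
  rho_obs <- cor(rank(x), rank(y[1, ]))
  rhos <- apply(perms, 1, function(pp) cor(rank(x), rank(y[1, ])[pp]))
  expect_equal(scr$p, mean(abs(rhos) >= abs(rho_obs) - 1e-12))
  # no-ties exact p also matches cor.test's exact null
  ref <- cor.test(x, y[1, ], method = "spearman", exact = TRUE)
  expect_equal(scr$p, ref$p.value, tolerance = 1e-12)
})

test_that("screen handles missing values, constants and null drugs", {
  set.seed(16)
  p <- setNames(runif(20), paste0("c", 1:20))
  auc <- rbind(d_null = rnorm(20), d_const = rep(2, 20),
               d_na = c(rnorm(2), rep(NA, 18)))
  colnames(auc) <- names(p)
  scr <- spearman_screen(p, auc)
  expect_gt(scr$p[scr$drug_id == "d_null"], 0.001)
  expect_true(is.na(scr$rho[scr$drug_id == "d_const"]))
  expect_true(is.na(scr$rho[scr$drug_id == "d_na"]))
  expect_identical(scr$n[scr$drug_id == "d_na"], 2L)
  # rho invariant under strictly monotone transforms of either side
  auc2 <- auc; auc2["d_null", ] <- exp(auc["d_null", ])
  expect_equal(spearman_screen(p^3, auc2)$rho[1], scr$rho[1])
})

test_that("concordant hits recover planted drugs across two panels", {
  set.seed(17)
  p1 <- setNames(runif(40), sprintf("a%02d", 1:40))
  p2 <- setNames(runif(40), sprintf("b%02d", 1:40))
  cfg <- drug_panel_config()
  s1 <- spearman_screen(p1, generate_drug_panel(p1, cfg, 201L), "panelA")
  s2 <- spearman_screen(p2, generate_drug_panel(p2, cfg, 202L), "panelB")
  hits <- concordant_hits(list(s1, s2))
  expect_setequal(hits, c("DRUG01", "DRUG02", "DRUG03"))
  # degenerate threshold and wrong sign give empty lists
  expect_length(concordant_hits(list(s1, s2), alpha = 0), 0)
  expect_length(concordant_hits(list(s1, s2), sign = "positive"), 0)
  expect_error(concordant_hits(list(s1)), "2 datasets")
})

test_that("GSEA running sum matches brute force on a 6-gene toy", {
  ranked <- setNames(c(3, 2, 1, -1, -2, -3), paste0("g", 1:6))
  set <- c("g1", "g3")
  res <- preranked_gsea(ranked, set, weight = 1, n_permutations = 100,
                        seed = 1L)
  # hand running sum: hits at positions 1 and 3 with |metric| 3 and 1
  inc <- c(3, 0, 1, 0, 0, 0) / 4
  dec <- c(0, 1, 0, 1, 1, 1) / 4
  run <- cumsum(inc - dec)
  expect_equal(res$es, run[which.max(abs(run))], tolerance = 1e-12)
  # a set of the top-|S| genes is maximally enriched among size-2 sets
  top <- preranked_gsea(ranked, c("g1", "g2"), n_permutations = 100,
                        seed = 1L)
  combos <- combn(names(ranked), 2)
  all_es <- apply(combos, 2, function(s)
    preranked_gsea(ranked, s, n_permutations = 1, seed = 1L)$es)
  expect_gt(top$es, 0)
  expect_equal(top$es, max(all_es), tolerance = 1e-12)
})

test_that("weight 0 reduces to the classical KS statistic", {
  set.seed(18)
  ranked <- setNames(rnorm(20), paste0("g", 1:20))
  set <- sample(names(ranked), 6)
  res <- preranked_gsea(ranked, set, weight = 0, n_permutations = 10,
                        seed = 2L)
  # brute force unweighted running sum
  ord <- names(sort(ranked, decreasing = TRUE))
  hit <- ord %in% set
  run <- cumsum(ifelse(hit, 1 / 6, -1 / 14))
  expect_equal(res$es, run[which.max(abs(run))], tolerance = 1e-12)
})

test_that("GSEA permutation p has the correct floor and is reproducible", {
  set.seed(19)
  ranked <- setNames(sort(rnorm(50), decreasing = TRUE), paste0("g", 1:50))
  res <- preranked_gsea(ranked, paste0("g", 1:8), n_permutations = 200,
                        seed = 7L)
  expect_gte(res$p, 1 / 201)
  expect_lte(res$p, 1)
  res2 <- preranked_gsea(ranked, paste0("g", 1:8), n_permutations = 200,
                         seed = 7L)
  expect_identical(res$p, res2$p)
  expect_identical(res$nes, res2$nes)
  expect_error(preranked_gsea(ranked, "absent"), "overlap")
  expect_error(preranked_gsea(ranked, names(ranked)), "strict subset")
})

test_that("independent labelings give a chi-square near its df", {
  set.seed(20)
  stats <- replicate(40, {
    a <- setNames(sample(1:3, 60, TRUE), paste0("s", 1:60))
    b <- setNames(sample(1:4, 60, TRUE), paste0("s", 1:60))
    ct <- cross_tabulate(a, b)
    suppressWarnings(chisq.test(unclass(ct))$statistic)
  })
  expect_equal(mean(stats), 6, tolerance = 0.35 * 6)  # df = (3-1)(4-1)
})
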