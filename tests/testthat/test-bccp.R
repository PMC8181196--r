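toy_model <- function(mu_in = 1, mu_out = -1, sd = 1, prior = 0.5,
                      w = c(gA = 1, gB = -1)) {
  lncsubtype:::new_bccp_model(1L, w, mu_in, mu_out, sd, prior)
}

test_that("compound score is the weighted sum over covered genes", {
  m <- toy_model()
  expect_equal(compound_score(m, c(gA = 2, gB = 3)), -1)
  expect_equal(compound_score(m, c(gA = 0, gB = 0)), 0)
  # linearity in the weights
  m2 <- toy_model(w = c(gA = 2, gB = -2))
  expect_equal(compound_score(m2, c(gA = 2, gB = 3)),
               2 * compound_score(m, c(gA = 2, gB = 3)))
  # missing genes contribute zero; below 50% coverage is an error
  expect_equal(compound_score(m, c(gA = 2, gX = 9)), 2)
  m3 <- toy_model(w = c(gA = 1, gB = 1, gC = 1, gD = 1))
  expect_error(compound_score(m3, c(gA = 1, gX = 1)), "25%")
})

test_that("posterior follows the Gaussian likelihood-ratio closed form", {
  m <- toy_model()
  expect_equal(posterior(m, 0), 0.5)                       # midpoint
  expect_equal(posterior(m, 1), 1 / (1 + exp(-2)))          # closed form
  expect_equal(posterior(m, 1), 0.8807971, tolerance = 1e-6)
  # uninformative model returns the prior everywhere
  flat <- toy_model(mu_in = 0, mu_out = 0, prior = 0.3)
  expect_equal(posterior(flat, c(-5, 0, 7)), rep(0.3, 3))
  # monotone increasing in score when mu_in > mu_out, decreasing otherwise
  s <- seq(-4, 4, length.out = 50)
  expect_true(all(diff(posterior(m, s)) > 0))
  rev <- toy_model(mu_in = -1, mu_out = 1)
  expect_true(all(diff(posterior(rev, s)) < 0))
  # finite even at extreme scores
  expect_true(all(is.finite(posterior(m, c(-1e4, 1e4)))))
})

test_that("training reproduces brute-force class means and pooled SD", {
  co <- small_cohort(seed = 16L, k = 2L, n = 30L)
  z <- zscore_genes(co$mrna)
  sig <- build_all_signatures(co$mrna, co$labels)[[1]]
  m <- train_binary(z, co$labels, 1, sig)
  # brute force: loop over samples and genes
  scores <- vapply(sample_ids(z), function(s)
    compound_score(m, z$values[, s]), numeric(1))
  in_s <- scores[co$labels == 1]; out_s <- scores[co$labels != 1]
  expect_equal(m$score_mean_in, mean(in_s), tolerance = 1e-10)
  expect_equal(m$score_mean_out, mean(out_s), tolerance = 1e-10)
  pooled <- sqrt(((length(in_s) - 1) * var(in_s) +
                  (length(out_s) - 1) * var(out_s)) /
                 (length(scores) - 2))
  expect_equal(m$score_sd, pooled, tolerance = 1e-10)
  # separable training data gives near-1 posteriors for in-class samples
  expect_true(all(posterior(m, in_s) > 0.99))
})

test_that("permuted labels destroy the class separation", {
  co <- small_cohort(seed = 17L, k = 2L, n = 60L)
  z <- zscore_genes(co$mrna)
  set.seed(5)
  perm <- setNames(sample(co$labels), names(co$labels))
  st <- ovr_t_test(co$mrna, perm, 1)
  sig <- suppressWarnings(build_signature(st, 1, p_threshold = 0.2))
  m <- train_binary(z, perm, 1, sig)
  real <- train_binary(z, co$labels, 1,
                       build_all_signatures(co$mrna, co$labels)[[1]])
  sep <- function(mm) abs(mm$score_mean_in - mm$score_mean_out) / mm$score_sd
  expect_lt(sep(m), sep(real) / 4)
})

test_that("multiclass training gives raw one-vs-rest posteriors", {
  co <- small_cohort(seed = 18L)
  z <- zscore_genes(co$mrna)
  sigs <- build_all_signatures(co$mrna, co$labels)
  models <- train_multiclass(z, co$labels, sigs)
  pred <- predict_subtypes(models, z)
  # training argmax recovers the training labels at high accuracy
  expect_gte(mean(pred$hard_label == co$labels[pred$sample_id]), 0.95)
  # one-vs-rest posteriors are raw, not renormalized: three
  # uninformative models each return their own prior, so the K
  # posteriors of a sample sum to K * prior, not to 1
  flat <- lapply(1:3, function(s)
    lncsubtype:::new_bccp_model(s, c(gA = 1), 0, 0, 1, 0.5))
  xf <- em(matrix(rnorm(3), 1, 3, dimnames = list("gA", paste0("t", 1:3))))
  pf <- predict_subtypes(flat, xf)
  expect_equal(rowSums(pf[, paste0("prob_", 1:3)]), rep(1.5, 3),
               ignore_attr = TRUE)
  # determinism
  pred2 <- predict_subtypes(train_multiclass(z, co$labels, sigs), z)
  expect_identical(pred, pred2)
})

test_that("prediction absorbs additive batch shifts via z-scoring", {
  co <- small_cohort(seed = 19L)
  sigs <- build_all_signatures(co$mrna, co$labels)
  models <- train_multiclass(zscore_genes(co$mrna), co$labels, sigs)
  test <- apply_batch_shift(co$mrna, 2, seed = 77L)
  pred <- predict_subtypes(models, zscore_genes(test))
  expect_gte(mean(pred$hard_label == co$labels[pred$sample_id]), 0.9)
  # sample order invariance
  set.seed(6)
  shuf <- test
  shuf$values <- shuf$values[, sample(ncol(shuf$values))]
  pred2 <- predict_subtypes(models, zscore_genes(shuf))
  rownames(pred) <- pred$sample_id; rownames(pred2) <- pred2$sample_id
  expect_equal(pred2[pred$sample_id, ], pred, ignore_attr = TRUE)
})

test_that("predicting all-zero signature genes returns posterior at 0", {
  m <- toy_model()
  x <- em(matrix(0, 2, 3, dimnames = list(c("gA", "gB"), paste0("s", 1:3))))
  pred <- predict_subtypes(list(m), x)
  expect_equal(pred$prob_1, rep(posterior(m, 0), 3))
})

test_that("rank AUC equals brute-force pair counting", {
  set.seed(8)
  for (i in 1:5) {
    score <- sample(round(rnorm(10), 1))  # rounding forces some ties
    truth <- sample(c(rep(TRUE, 4), rep(FALSE, 6)))
    pairs <- expand.grid(p = which(truth), n = which(!truth))
    brute <- mean(ifelse(score[pairs$p] > score[pairs$n], 1,
                         ifelse(score[pairs$p] == score[pairs$n], 0.5, 0)))
    expect_equal(auc_rank(score, truth), brute, tolerance = 1e-12)
  }
  expect_equal(auc_rank(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)   # perfect
  expect_error(auc_rank(1:3, c(1, 1, 1)), "both")
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(9)
  score <- rnorm(30)
  truth <- rbinom(30, 1, 0.4)
  a <- auc_rank(score, truth)
  expect_equal(auc_rank(exp(score), truth), a)
  expect_equal(auc_rank(qlogis(plogis(score)), truth), a, tolerance = 1e-12)
})

test_that("fast LOOCV equals naive re-derivation on a small cohort", {
  co <- small_cohort(seed = 20L, k = 2L, n = 24L, n_mrna = 80L,
                     markers = 10L)
  fast <- loocv_auc(co$mrna, co$labels, p_threshold = 0.01, max_genes = 20)
  # naive path: rebuild everything per held-out sample with the public API
  naive <- matrix(NA_real_, 24, 2)
  for (j in seq_len(24)) {
    train <- em(co$mrna$values[, -j])
    lab_t <- co$labels[sample_ids(train)]
    sigs <- suppressWarnings(
      build_all_signatures(train, lab_t, p_threshold = 0.01,
                           max_genes = 20))
    mu <- rowMeans(train$values)
    sd_ <- apply(train$values, 1, sd)
    zt <- train; zt$values <- (train$values - mu) / sd_
    models <- train_multiclass(zt, lab_t, sigs)
    zj <- (co$mrna$values[, j] - mu) / sd_
    for (s in 1:2)
      naive[j, s] <- posterior(models[[s]],
                               compound_score(models[[s]], zj))
  }
  expect_equal(unname(fast$posteriors), naive, tolerance = 1e-10)
  for (s in 1:2)
    expect_equal(unname(fast$auc[s]),
                 auc_rank(naive[, s], co$labels == s), tolerance = 1e-12)
})

test_that("LOOCV separates real structure from noise", {
  co <- small_cohort(seed = 25L, k = 2L, n = 40L, effect = 2)
  res <- loocv_auc(co$mrna, co$labels, p_threshold = 0.001)
  expect_true(all(res$auc > 0.9))
  resub <- resubstitution_auc(co$mrna, co$labels)
  expect_true(all(resub >= res$auc - 0.05))  # resubstitution is optimistic
})
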