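#' Bayesian compound covariate predictor (BCCP)
#'
#' A binary one-vs-rest classifier in the compound covariate tradition:
#' a sample's compound score is the weighted sum of its signature-gene
#' expression with weights equal to the training t-statistics, and the
#' two classes are modeled as Gaussians with class-specific means and a
#' shared (pooled within-class) SD on the score axis, yielding a closed
#' form posterior probability of class membership.
#'
#' @name bccp
NULL

new_bccp_model <- function(subtype, gene_weights, score_mean_in,
                           score_mean_out, score_sd, prior_in) {
  stopifnot(length(gene_weights) > 0, score_sd > 0,
            prior_in > 0, prior_in < 1)
  structure(list(subtype = subtype, gene_weights = gene_weights,
                 score_mean_in = score_mean_in,
                 score_mean_out = score_mean_out,
                 score_sd = score_sd, prior_in = prior_in),
            class = "bccp_model")
}

#' @export
print.bccp_model <- function(x, ...) {
  cat(sprintf(
    "<bccp_model> subtype %s: %d genes, mu_in=%.3f mu_out=%.3f sd=%.3f pi=%.2f\n",
    x$subtype, length(x$gene_weights), x$score_mean_in, x$score_mean_out,
    x$score_sd, x$prior_in))
  invisible(x)
}

#' Compound covariate score of one sample
#'
#' `score = sum_g t_g * x_g` over the model's signature genes covered by
#' the profile. Genes absent from the profile contribute 0 (their
#' z-scored expectation); coverage below 50% of the signature is an
#' error rather than a silent degradation.
#'
#' @param model a `bccp_model`.
#' @param sample_profile named numeric vector of (z-scored) expression.
#' @return scalar score.
#' @export
compound_score <- function(model, sample_profile) {
  w <- model$gene_weights
  covered <- names(w)[names(w) %in% names(sample_profile)]
  frac <- length(covered) / length(w)
  if (frac < 0.5)
    stop(sprintf("profile covers only %.0f%% of subtype-%s signature genes",
                 100 * frac, model$subtype))
  sum(w[covered] * sample_profile[covered])
}

#' Train a one-vs-rest BCCP model
#'
#' Weights are the signature genes' training t-statistics; compound
#' scores are computed for every training sample; the class-conditional
#' Gaussians take the in-class and out-class score means and, by
#' default, a pooled within-class SD (`shared_variance = FALSE` keeps
#' per-class SDs, in which case the posterior uses each class's own SD).
#'
#' @param x an `expr_matrix`, z-scored per gene (see [zscore_genes()]).
#' @param labels named integer subtype labels.
#' @param subtype the "in" class index.
#' @param signature a `subtype_signature` for this subtype.
#' @param prior_in prior probability of the in-class (default 0.5; the
#'   deliberate non-empirical choice that keeps one-vs-rest posteriors
#'   from being swamped by the majority class).
#' @param shared_variance pool the within-class score SD (default).
#' @return a `bccp_model`.
#' @export
train_binary <- function(x, labels, subtype, signature, prior_in = 0.5,
                         shared_variance = TRUE) {
  stopifnot(is_expr_matrix(x), inherits(signature, "subtype_signature"))
  labels <- labels[sample_ids(x)]
  if (anyNA(labels)) stop("`labels` must cover every sample in the matrix")
  if (nrow(signature$genes) == 0L) stop("cannot train on an empty signature")
  w <- stats::setNames(signature$genes$t_statistic, signature$genes$gene_id)
  present <- names(w)[names(w) %in% gene_ids(x)]
  if (length(present) / length(w) < 0.5)
    stop("training matrix covers <50% of the signature genes")
  w <- w[present]
  scores <- as.vector(crossprod(x$values[present, , drop = FALSE], w))
  in_s <- scores[labels == subtype]
  out_s <- scores[labels != subtype]
  if (length(in_s) < 2 || length(out_s) < 2)
    stop("both classes need at least 2 samples")
  pooled_var <- ((length(in_s) - 1) * stats::var(in_s) +
                 (length(out_s) - 1) * stats::var(out_s)) /
    (length(in_s) + length(out_s) - 2)
  if (pooled_var <= 0) stop("degenerate (zero) pooled score SD")
  m <- new_bccp_model(subtype, w, mean(in_s), mean(out_s),
                      sqrt(pooled_var), prior_in)
  if (!shared_variance) {
    m$sd_in <- stats::sd(in_s)
    m$sd_out <- stats::sd(out_s)
    if (m$sd_in <= 0 || m$sd_out <= 0) stop("degenerate class score SD")
  }
  m
}

#' Posterior probability of class membership given a score
#'
#' `P(in | s) = pi * phi(s; mu_in, sigma) /
#'  (pi * phi(s; mu_in, sigma) + (1 - pi) * phi(s; mu_out, sigma))`
#' with shared `sigma = score_sd` (or per-class SDs if the model was
#' trained without variance pooling). Computed on the log scale, so it
#' is finite and stable for any score.
#'
#' @param model a `bccp_model`.
#' @param score numeric vector of compound scores.
#' @return posterior probabilities in \[0, 1\].
#' @export
posterior <- function(model, score) {
  sd_in <- if (is.null(model$sd_in)) model$score_sd else model$sd_in
  sd_out <- if (is.null(model$sd_out)) model$score_sd else model$sd_out
  l_in <- stats::dnorm(score, model$score_mean_in, sd_in, log = TRUE) +
    log(model$prior_in)
  l_out <- stats::dnorm(score, model$score_mean_out, sd_out, log = TRUE) +
    log(1 - model$prior_in)
  1 / (1 + exp(l_out - l_in))
}

#' Train all K one-vs-rest BCCP models
#'
#' @inheritParams train_binary
#' @param signatures list of `subtype_signature`, one per subtype index.
#' @param priors per-subtype in-class priors (recycled; default 0.5).
#' @return list of `bccp_model`, length K.
#' @export
train_multiclass <- function(x, labels, signatures, priors = 0.5,
                             shared_variance = TRUE) {
  k <- length(signatures)
  priors <- rep_len(priors, k)
  lapply(seq_len(k), function(s)
    train_binary(x, labels, signatures[[s]]$subtype, signatures[[s]],
                 prior_in = priors[s], shared_variance = shared_variance))
}

#' Assign samples to subtypes by Bayesian probability scores
#'
#' Scores every sample under each one-vs-rest model and reports the K
#' raw posteriors plus the argmax hard label (ties go to the smallest
#' subtype index). Posteriors are one-vs-rest, not renormalized: each is
#' interpretable on its own as the sample's membership probability for
#' that subtype, which downstream analyses use directly.
#'
#' @param models list of `bccp_model` from [train_multiclass()].
#' @param x an `expr_matrix`, z-scored per gene within its own cohort.
#' @return data.frame with `sample_id`, `hard_label`, and one
#'   `prob_<k>` column per subtype.
#' @export
predict_subtypes <- function(models, x) {
  stopifnot(is_expr_matrix(x))
  probs <- vapply(models, function(m) {
    w <- m$gene_weights
    present <- names(w)[names(w) %in% gene_ids(x)]
    frac <- length(present) / length(w)
    if (frac < 0.5)
      stop(sprintf(
        "cohort covers only %.0f%% of subtype-%s signature genes",
        100 * frac, m$subtype))
    scores <- as.vector(crossprod(x$values[present, , drop = FALSE],
                                  w[present]))
    posterior(m, scores)
  }, numeric(ncol(x$values)))
  probs <- matrix(probs, ncol = length(models))
  hard <- max.col(probs, ties.method = "first")
  out <- data.frame(sample_id = sample_ids(x),
                    hard_label = vapply(models, `[[`, numeric(1),
                                        "subtype")[hard],
                    stringsAsFactors = FALSE)
  colnames(probs) <- paste0("prob_", vapply(models, `[[`, numeric(1),
                                            "subtype"))
  cbind(out, probs)
}

#' AUROC by the rank statistic
#'
#' Area under the ROC curve of `score` against binary `truth`, computed
#' as the normalized Wilcoxon rank sum with mid-ranks for ties: the
#' probability that a random positive outranks a random negative
#' (ties counting one half).
#'
#' @param score numeric predictor.
#' @param truth logical or 0/1 class membership.
#' @return scalar AUC in \[0, 1\].
#' @export
auc_rank <- function(score, truth) {
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) stop("need both positives and negatives")
  r <- rank(score)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Leave-one-out cross-validated per-subtype AUROC
#'
#' For each held-out sample the whole supervised chain is re-derived on
#' the remaining samples -- one-vs-rest t-tests, signature selection,
#' per-gene z-scoring statistics, and BCCP model fitting -- so no
#' information from the held-out sample leaks into its posteriors. The
#' held-out sample is z-scored with the training genes' means/SDs and
#' scored under all K models. Per-subtype AUROC is then the rank-AUC of
#' that subtype's posterior against subtype membership.
#'
#' Group statistics are updated by sum/sum-of-squares downdating rather
#' than recomputation, which makes the loop linear in the matrix size;
#' equality with the naive re-derivation path is part of the test suite.
#'
#' @param x an `expr_matrix` of raw (not z-scored) log2 expression.
#' @param labels named integer subtype labels (e.g. cluster labels).
#' @param p_threshold,max_genes signature selection parameters.
#' @param priors per-subtype in-class priors.
#' @return list with `auc` (named per-subtype vector) and `posteriors`
#'   (samples x K matrix of held-out posteriors).
#' @export
loocv_auc <- function(x, labels, p_threshold = 0.001, max_genes = 200,
                      priors = 0.5) {
  stopifnot(is_expr_matrix(x))
  labels <- labels[sample_ids(x)]
  if (anyNA(labels)) stop("`labels` must cover every sample in the matrix")
  subtypes <- sort(unique(labels))
  k <- length(subtypes)
  if (any(table(labels) < 3))
    stop("every subtype needs at least 3 samples for LOOCV")
  priors <- rep_len(priors, k)
  X <- x$values
  n <- ncol(X); g <- nrow(X)
  gid <- rownames(X)
  # cached per-class sums and sums of squares for O(g) downdating
  S_tot <- rowSums(X); Q_tot <- rowSums(X * X)
  S_cls <- vapply(subtypes, function(s)
    rowSums(X[, labels == s, drop = FALSE]), numeric(g))
  Q_cls <- vapply(subtypes, function(s) {
    xs <- X[, labels == s, drop = FALSE]; rowSums(xs * xs)
  }, numeric(g))
  n_cls <- as.vector(table(factor(labels, levels = subtypes)))

  post <- matrix(NA_real_, n, k,
                 dimnames = list(colnames(X), paste0("prob_", subtypes)))
  for (j in seq_len(n)) {
    xj <- X[, j]
    cj <- match(labels[j], subtypes)
    nt <- n - 1L
    St <- S_tot - xj; Qt <- Q_tot - xj * xj
    mu_t <- St / nt
    var_t <- pmax(Qt - nt * mu_t * mu_t, 0) / (nt - 1)
    sd_t <- sqrt(var_t)
    const <- sd_t == 0
    sd_t[const] <- 1
    z_j <- (xj - mu_t) / sd_t
    z_j[const] <- 0
    for (s in seq_len(k)) {
      S_in <- S_cls[, s]; Q_in <- Q_cls[, s]; n_in <- n_cls[s]
      if (s == cj) {
        S_in <- S_in - xj; Q_in <- Q_in - xj * xj; n_in <- n_in - 1L
      }
      n_out <- nt - n_in
      S_out <- St - S_in; Q_out <- Qt - Q_in
      m1 <- S_in / n_in; m0 <- S_out / n_out
      v1 <- pmax(Q_in - n_in * m1 * m1, 0) / (n_in - 1)
      v0 <- pmax(Q_out - n_out * m0 * m0, 0) / (n_out - 1)
      sp2 <- ((n_in - 1) * v1 + (n_out - 1) * v0) / (nt - 2)
      se <- sqrt(sp2 * (1 / n_in + 1 / n_out))
      diff <- m1 - m0
      t_stat <- ifelse(se == 0, ifelse(diff == 0, 0, sign(diff) * Inf),
                       diff / se)
      p <- ifelse(is.finite(t_stat), 2 * stats::pt(-abs(t_stat), nt - 2),
                  ifelse(t_stat == 0, 1, 0))
      keep <- which(p < p_threshold & diff > 0 & is.finite(t_stat))
      if (length(keep) == 0L) { post[j, s] <- NA_real_; next }
      keep <- keep[order(-diff[keep], gid[keep])]
      keep <- utils::head(keep, max_genes)
      w <- t_stat[keep]
      # z-scored training block restricted to signature genes
      Zs <- (X[keep, -j, drop = FALSE] - mu_t[keep]) / sd_t[keep]
      Zs[const[keep], ] <- 0
      scores <- as.vector(crossprod(Zs, w))
      lab_t <- labels[-j]
      in_s <- scores[lab_t == subtypes[s]]
      out_s <- scores[lab_t != subtypes[s]]
      pooled <- ((length(in_s) - 1) * stats::var(in_s) +
                 (length(out_s) - 1) * stats::var(out_s)) / (nt - 2)
      if (pooled <= 0) { post[j, s] <- NA_real_; next }
      m_tmp <- new_bccp_model(subtypes[s],
                              stats::setNames(w, gid[keep]),
                              mean(in_s), mean(out_s), sqrt(pooled),
                              priors[s])
      post[j, s] <- posterior(m_tmp, sum(w * z_j[keep]))
    }
  }
  auc <- vapply(seq_len(k), function(s) {
    p <- post[, s]
    ok <- !is.na(p)
    auc_rank(p[ok], labels[ok] == subtypes[s])
  }, numeric(1))
  names(auc) <- paste0("subtype_", subtypes)
  list(auc = auc, posteriors = post)
}

#' Resubstitution per-subtype AUROC
#'
#' Trains on the full cohort and evaluates on the same samples --
#' reported separately from [loocv_auc()] because it is optimistically
#' biased; provided for comparison with the cross-validated figures.
#'
#' @inheritParams loocv_auc
#' @return named per-subtype AUC vector.
#' @export
resubstitution_auc <- function(x, labels, p_threshold = 0.001,
                               max_genes = 200, priors = 0.5) {
  labels <- labels[sample_ids(x)]
  sigs <- build_all_signatures(x, labels, p_threshold, max_genes)
  z <- zscore_genes(x)
  models <- train_multiclass(z, labels, sigs, priors)
  pred <- predict_subtypes(models, z)
  subtypes <- sort(unique(labels))
  auc <- vapply(subtypes, function(s)
    auc_rank(pred[[paste0("prob_", s)]], labels == s), numeric(1))
  names(auc) <- paste0("subtype_", subtypes)
  auc
}
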