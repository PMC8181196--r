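#' Cross-tabulate two subtype assignments
#'
#' Counts samples shared between every pair of classes of two labelings
#' (the data behind a chord diagram): `counts[i, j]` is the number of
#' samples labeled `i` in A and `j` in B, over the intersection of
#' sample IDs.
#'
#' @param assign_a,assign_b named label vectors (names = sample IDs).
#' @return integer matrix with A's classes in rows, B's in columns;
#'   attribute `n_common` records the intersection size.
#' @export
cross_tabulate <- function(assign_a, assign_b) {
  common <- intersect(names(assign_a), names(assign_b))
  if (length(common) == 0L) stop("empty sample intersection")
  a <- factor(assign_a[common])
  b <- factor(assign_b[common])
  counts <- unclass(table(a, b))
  dimnames(counts) <- list(levels(a), levels(b))
  attr(counts, "n_common") <- length(common)
  counts
}

# mid-rank Spearman rho
spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

# all permutations of 1..n (n <= 9), one per row
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (pos in seq_len(n)) {
    rows <- (pos - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, pos] <- n
    out[rows, -pos] <- sub
  }
  out
}

spearman_p <- function(rho, x, y) {
  n <- length(x)
  if (n >= 10) {
    if (abs(rho) >= 1) return(0)
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), n - 2)
  } else {
    # exact permutation null over all n! orderings of y
    perms <- all_permutations(n)
    ry <- rank(y)
    rhos <- apply(perms, 1, function(p) spearman_rho(x, ry[p]))
    mean(abs(rhos) >= abs(rho) - 1e-12)
  }
}

#' Spearman screen of drug AUC against subtype probability
#'
#' For every drug in the panel, correlates its AUC values with each cell
#' line's subtype-membership probability using mid-rank Spearman rho.
#' Missing AUC values are dropped pairwise; drugs with fewer than 4
#' complete pairs or constant ranks are reported with NA. Two-sided
#' p-values use the t approximation for n >= 10 and the exact
#' permutation null for smaller n.
#'
#' @param probabilities named numeric vector, one probability per cell
#'   line.
#' @param auc_table numeric matrix, drugs x cell lines.
#' @param dataset_tag free-text tag recorded per row.
#' @return data.frame with `drug_id`, `rho`, `p`, `n`, `dataset_tag`.
#' @export
spearman_screen <- function(probabilities, auc_table,
                            dataset_tag = "panel") {
  common <- intersect(names(probabilities), colnames(auc_table))
  if (length(common) == 0L) stop("no shared cell lines")
  p <- probabilities[common]
  res <- lapply(rownames(auc_table), function(d) {
    auc <- auc_table[d, common]
    ok <- !is.na(auc) & !is.na(p)
    n <- sum(ok)
    if (n < 4)
      return(data.frame(drug_id = d, rho = NA_real_, p = NA_real_,
                        n = n, dataset_tag = dataset_tag))
    rho <- spearman_rho(p[ok], auc[ok])
    pv <- if (is.na(rho)) NA_real_ else spearman_p(rho, p[ok], auc[ok])
    data.frame(drug_id = d, rho = rho, p = pv, n = n,
               dataset_tag = dataset_tag, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Drugs significant with a consistent sign in every dataset
#'
#' Intersects two or more Spearman screens and keeps the drugs whose
#' correlation is significant (raw `p < alpha`) AND of the required sign
#' in every dataset -- the concordance rule for calling a drug
#' preferentially active against one subtype.
#'
#' @param screens list (length >= 2) of [spearman_screen()] results.
#' @param alpha per-dataset significance gate (default 0.05).
#' @param sign `"negative"` (default: lower AUC, i.e. higher
#'   sensitivity, with higher probability) or `"positive"`.
#' @return character vector of concordant drug IDs.
#' @export
concordant_hits <- function(screens, alpha = 0.05,
                            sign = c("negative", "positive")) {
  sign <- match.arg(sign)
  if (length(screens) < 2) stop("need screens from at least 2 datasets")
  shared <- Reduce(intersect, lapply(screens, `[[`, "drug_id"))
  if (length(shared) == 0L) stop("no shared drug IDs across datasets")
  ok <- vapply(shared, function(d) {
    all(vapply(screens, function(s) {
      row <- s[s$drug_id == d, ]
      if (nrow(row) != 1L || is.na(row$rho) || is.na(row$p)) return(FALSE)
      row$p < alpha &&
        if (sign == "negative") row$rho < 0 else row$rho > 0
    }, logical(1)))
  }, logical(1))
  shared[ok]
}

gsea_es <- function(metric_sorted, in_set, weight) {
  n <- length(metric_sorted)
  nh <- sum(in_set)
  hit_w <- abs(metric_sorted)^weight * in_set
  denom <- sum(hit_w)
  if (denom == 0) hit_w <- in_set / nh else hit_w <- hit_w / denom
  miss_w <- (!in_set) / (n - nh)
  running <- cumsum(hit_w - miss_w)
  unname(running[which.max(abs(running))])
}

#' Pre-ranked gene set enrichment
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment of a gene set in
#' a ranked list: walking down the list sorted by decreasing metric,
#' set members increment the running sum proportionally to
#' `|metric|^weight` (normalized over set members) and non-members
#' decrement it uniformly; the enrichment score (ES) is the maximum
#' signed deviation from zero. `weight = 0` recovers the classical
#' unweighted KS statistic. Significance is assessed by permuting set
#' membership over genes (the pre-ranked scheme, appropriate when
#' phenotype permutation is unavailable); NES divides the ES by the
#' mean |ES| of same-sign permutations.
#'
#' @param ranked named numeric vector: per-gene ranking metric.
#' @param gene_set character vector of set member gene IDs.
#' @param weight running-sum exponent (default 1).
#' @param n_permutations membership permutations (default 1000).
#' @param seed integer RNG seed for the permutations.
#' @return list of class `gsea_result` with `es`, `nes`, `p`,
#'   `n_permutations`, `set_size`.
#' @export
preranked_gsea <- function(ranked, gene_set, weight = 1,
                           n_permutations = 1000, seed = 1L) {
  genes <- names(ranked)
  in_set_ids <- intersect(genes, gene_set)
  if (length(in_set_ids) == 0L) stop("gene set does not overlap the ranking")
  if (length(in_set_ids) >= length(genes))
    stop("gene set must be a strict subset of the ranked list")
  ord <- order(ranked, decreasing = TRUE)
  metric <- ranked[ord]
  in_set <- names(metric) %in% in_set_ids
  es <- gsea_es(metric, in_set, weight)
  nh <- sum(in_set)
  set.seed(as.integer(seed))
  perm_es <- vapply(seq_len(n_permutations), function(i) {
    idx <- sample.int(length(metric), nh)
    flag <- logical(length(metric))
    flag[idx] <- TRUE
    gsea_es(metric, flag, weight)
  }, numeric(1))
  same_sign <- perm_es[sign(perm_es) == sign(es)]
  p <- (1 + sum(abs(same_sign) >= abs(es))) / (n_permutations + 1)
  nes <- if (length(same_sign) > 0) es / mean(abs(same_sign)) else NA_real_
  structure(list(es = es, nes = nes, p = p,
                 n_permutations = n_permutations, set_size = nh),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("<gsea_result> ES=%.3f NES=%.3f p=%.4g (%d genes, %d perms)\n",
              x$es, x$nes, x$p, x$set_size, x$n_permutations))
  invisible(x)
}
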