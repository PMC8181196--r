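#' Select the most variable genes
#'
#' Returns the `n_top` gene IDs with the largest sample standard
#' deviation across samples; ties are broken lexicographically by gene
#' ID so the selection is deterministic.
#'
#' @param x an `expr_matrix`.
#' @param n_top number of genes to keep, in `1..n_genes`.
#' @return character vector of gene IDs, SD-descending.
#' @export
select_variable_genes <- function(x, n_top) {
  stopifnot(is_expr_matrix(x))
  if (n_top <= 0) stop("`n_top` must be positive")
  if (n_top > nrow(x$values)) stop("`n_top` exceeds the number of genes")
  sds <- row_sds(x$values)
  ids <- gene_ids(x)
  ord <- order(-sds, ids)
  ids[ord][seq_len(n_top)]
}

sample_distance <- function(values, distance) {
  if (distance == "correlation") {
    v <- row_sds(t(values))   # per-sample SD over selected genes
    if (any(v == 0))
      stop("zero-variance sample profile under correlation distance: ",
           colnames(values)[which(v == 0)[1L]])
    stats::as.dist(1 - stats::cor(values))
  } else {
    stats::dist(t(values))
  }
}

#' Hierarchical clustering of samples into K subtypes
#'
#' Clusters sample profiles over a chosen gene set with either
#' correlation distance (1 - Pearson r between profiles) or Euclidean
#' distance, cuts the tree at `k`, and renumbers the groups 1..k by
#' decreasing size (ties broken by the lexicographically smallest sample
#' ID they contain) so labels are reproducible across runs.
#'
#' @param x an `expr_matrix`.
#' @param genes gene IDs to cluster on; defaults to all genes.
#' @param k number of clusters, >= 2.
#' @param distance `"correlation"` (default) or `"euclidean"`.
#' @param linkage `"average"` (default), `"complete"` or `"ward"`
#'   (Ward.D2 on the chosen distance).
#' @return list of class `clustering_result` with `labels` (named
#'   integer), `k`, `linkage_tree` (the `hclust` object), and
#'   `selected_genes`.
#' @export
hierarchical_cluster <- function(x, genes = gene_ids(x), k,
                                 distance = c("correlation", "euclidean"),
                                 linkage = c("average", "complete", "ward")) {
  stopifnot(is_expr_matrix(x))
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (k < 2) stop("`k` must be >= 2")
  if (k > ncol(x$values)) stop("`k` exceeds the number of samples")
  missing_genes <- setdiff(genes, gene_ids(x))
  if (length(missing_genes))
    stop("unknown gene IDs: ", paste(utils::head(missing_genes, 3),
                                     collapse = ", "))
  vals <- x$values[genes, , drop = FALSE]
  d <- sample_distance(vals, distance)
  method <- c(average = "average", complete = "complete",
              ward = "ward.D2")[[linkage]]
  tree <- stats::hclust(d, method = method)
  raw <- stats::cutree(tree, k = k)
  structure(list(labels = renumber_labels(raw), k = k,
                 linkage_tree = tree, selected_genes = genes,
                 distance = distance, linkage = linkage),
            class = "clustering_result")
}

# renumber cluster labels 1..k by decreasing size, ties by the smallest
# contained sample ID
renumber_labels <- function(raw) {
  ids <- names(raw)
  cl <- sort(unique(raw))
  size <- vapply(cl, function(c) sum(raw == c), integer(1))
  minid <- vapply(cl, function(c) min(ids[raw == c]), character(1))
  new_order <- cl[order(-size, minid)]
  out <- match(raw, new_order)
  names(out) <- ids
  out
}

#' Mean silhouette width across candidate K
#'
#' Clusters at each `k` in `k_range` with the stated distance/linkage
#' and reports the mean silhouette width computed on the same distance,
#' as a guide (never an automatic selector) for the number of subtypes.
#'
#' @inheritParams hierarchical_cluster
#' @param k_range integer vector of candidate K, within
#'   `[2, n_samples - 1]`.
#' @return data.frame with columns `k` and `mean_silhouette`, sorted by
#'   `k`.
#' @export
evaluate_k <- function(x, genes = gene_ids(x), k_range = 2:8,
                       distance = c("correlation", "euclidean"),
                       linkage = c("average", "complete", "ward")) {
  stopifnot(is_expr_matrix(x))
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  n <- ncol(x$values)
  if (any(k_range < 2) || any(k_range > n - 1))
    stop("`k_range` must lie within [2, n_samples - 1]")
  vals <- x$values[genes, , drop = FALSE]
  d <- sample_distance(vals, distance)
  method <- c(average = "average", complete = "complete",
              ward = "ward.D2")[[linkage]]
  tree <- stats::hclust(d, method = method)
  k_range <- sort(k_range)
  sil <- vapply(k_range, function(k) {
    lab <- stats::cutree(tree, k = k)
    mean(cluster::silhouette(lab, d)[, "sil_width"])
  }, numeric(1))
  data.frame(k = k_range, mean_silhouette = sil)
}
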