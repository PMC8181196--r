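#' Expression matrix container
#'
#' A light S3 container for a genes-by-samples matrix of log2 expression
#' values, tagged with the feature space it lives in (lncRNA or mRNA) and
#' a free-text cohort tag. Gene IDs are the rownames of `values`, sample
#' IDs the colnames; both must be unique.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   unique rownames and colnames.
#' @param feature_space `"lncRNA"` or `"mRNA"`.
#' @param cohort_tag free-text cohort / platform label.
#' @return an object of class `expr_matrix` with fields `values`,
#'   `feature_space`, `cohort_tag`.
#' @export
expression_matrix <- function(values, feature_space = c("lncRNA", "mRNA"),
                              cohort_tag = "cohort") {
  feature_space <- match.arg(feature_space)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene IDs in `values`")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs in `values`")
  structure(
    list(values = values, feature_space = feature_space,
         cohort_tag = cohort_tag),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples [%s, %s]\n",
              nrow(x$values), ncol(x$values), x$feature_space, x$cohort_tag))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x object to test.
#' @export
is_expr_matrix <- function(x) inherits(x, "expr_matrix")

gene_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Read a genes-by-samples expression TSV
#'
#' Expects tab-separated text: first row sample IDs, first column gene
#' IDs. Lines starting with `#` are ignored. Duplicate gene IDs are
#' collapsed by per-gene mean; rows with more than 20% missing values are
#' dropped; remaining missing cells are imputed by the per-gene mean of
#' the observed samples.
#'
#' @param path file path.
#' @param feature_space,cohort_tag passed to [expression_matrix()].
#' @return an `expr_matrix`.
#' @export
read_expression <- function(path, feature_space = c("lncRNA", "mRNA"),
                            cohort_tag = "cohort") {
  feature_space <- match.arg(feature_space)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           comment.char = "#", colClasses = "character",
                           row.names = NULL)
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("format error: empty or header-only expression file: ", path)
  genes <- raw[[1L]]
  samples <- colnames(raw)[-1L]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals) & vals != "" & toupper(vals) != "NA",
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("parse error: non-numeric cell at gene '%s', sample '%s'",
                 genes[bad[1L, 1L]], samples[bad[1L, 2L]]))
  dimnames(num) <- list(genes, samples)
  # collapse duplicated gene IDs by mean
  if (anyDuplicated(genes)) {
    num <- rowsum(num, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
  }
  # missingness policy: drop rows >20% NA, impute the rest by row mean
  na_frac <- rowMeans(is.na(num))
  num <- num[na_frac <= 0.2, , drop = FALSE]
  if (anyNA(num)) {
    rm_ <- rowMeans(num, na.rm = TRUE)
    idx <- which(is.na(num), arr.ind = TRUE)
    num[idx] <- rm_[idx[, 1L]]
  }
  expression_matrix(num, feature_space, cohort_tag)
}

#' Write an expression matrix as TSV
#'
#' Values are written with six decimal places; a `#` comment line records
#' the package version and cohort tag so written files are
#' self-describing. [read_expression()] round-trips these files.
#'
#' @param x an `expr_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(is_expr_matrix(x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# lncsubtype %s | feature_space=%s | cohort=%s",
                     pkg_version(), x$feature_space, x$cohort_tag), con)
  writeLines(paste(c("gene_id", sample_ids(x)), collapse = "\t"), con)
  body <- apply(x$values, 1L, function(v)
    paste(sprintf("%.6f", v), collapse = "\t"))
  writeLines(paste(gene_ids(x), body, sep = "\t"), con)
  invisible(path)
}

pkg_version <- function() {
  as.character(utils::packageVersion("lncsubtype"))
}

#' Median-center each gene
#'
#' Subtracts the per-gene median so every gene row has median zero --
#' the usual preprocessing before correlation-based sample clustering.
#'
#' @param x an `expr_matrix`.
#' @return an `expr_matrix` of identical shape.
#' @export
median_center_genes <- function(x) {
  stopifnot(is_expr_matrix(x))
  if (ncol(x$values) < 1L) stop("need at least one sample")
  med <- apply(x$values, 1L, stats::median)
  x$values <- x$values - med
  x
}

#' Z-score each gene
#'
#' Standardizes each gene row to mean 0 and sample (n-1) standard
#' deviation 1. Constant rows cannot be standardized; they are set to
#' all zeros and their IDs recorded in the `constant_genes` field. This
#' per-cohort standardization is the harmonization contract that lets a
#' model trained on one platform score samples from another.
#'
#' @param x an `expr_matrix` with at least two samples.
#' @return an `expr_matrix`; `$constant_genes` lists zeroed rows.
#' @export
zscore_genes <- function(x) {
  stopifnot(is_expr_matrix(x))
  if (ncol(x$values) < 2L) stop("z-scoring needs at least 2 samples")
  m <- rowMeans(x$values)
  s <- row_sds(x$values)
  const <- s == 0 | !is.finite(s)
  s[const] <- 1
  x$values <- (x$values - m) / s
  x$values[const, ] <- 0
  x$constant_genes <- gene_ids(x)[const]
  x
}

# row-wise sample SD without apply() overhead
row_sds <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  sqrt(pmax(rowSums(m * m) - n * mu * mu, 0) / (n - 1))
}

#' Restrict two expression matrices to their shared genes
#'
#' Both matrices are subset to the intersection of their gene IDs, in
#' lexicographic order, so a signature derived on one platform can be
#' applied to another.
#'
#' @param a,b `expr_matrix` objects in the same feature space.
#' @return list of the two restricted matrices.
#' @export
intersect_genes <- function(a, b) {
  stopifnot(is_expr_matrix(a), is_expr_matrix(b))
  if (a$feature_space != b$feature_space)
    stop("feature spaces differ: ", a$feature_space, " vs ", b$feature_space)
  shared <- sort(intersect(gene_ids(a), gene_ids(b)))
  if (length(shared) == 0L) stop("empty gene intersection")
  a$values <- a$values[shared, , drop = FALSE]
  b$values <- b$values[shared, , drop = FALSE]
  list(a = a, b = b)
}
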