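#' One-vs-rest two-class t-tests for every gene
#'
#' For each gene, compares samples of `subtype` against all remaining
#' samples with a pooled-variance (Student) two-sample t-test on
#' `n - 2` degrees of freedom, two-sided. The log ratio is the
#' difference of group means on the log2 scale (subtype minus rest), i.e.
#' the log2 fold change. Welch's unequal-variance form is available via
#' `var_equal = FALSE` for sensitivity analyses; the compound covariate
#' tradition this package follows uses the pooled form.
#'
#' @param x an `expr_matrix`.
#' @param labels named integer subtype labels covering the samples of
#'   `x`.
#' @param subtype the subtype index forming the "in" group.
#' @param var_equal pooled variance (default) or Welch.
#' @return data.frame with columns `gene_id`, `t_statistic`,
#'   `log_ratio`, `p_value`, one row per gene in input order.
#' @export
ovr_t_test <- function(x, labels, subtype, var_equal = TRUE) {
  stopifnot(is_expr_matrix(x))
  labels <- labels[sample_ids(x)]
  if (anyNA(labels)) stop("`labels` must cover every sample in the matrix")
  in_grp <- which(labels == subtype)
  out_grp <- which(labels != subtype)
  n1 <- length(in_grp); n0 <- length(out_grp)
  if (n1 < 2 || n0 < 2)
    stop("both the subtype and the rest need at least 2 samples")
  xi <- x$values[, in_grp, drop = FALSE]
  xo <- x$values[, out_grp, drop = FALSE]
  m1 <- rowMeans(xi); m0 <- rowMeans(xo)
  v1 <- pmax(rowSums(xi * xi) - n1 * m1 * m1, 0) / (n1 - 1)
  v0 <- pmax(rowSums(xo * xo) - n0 * m0 * m0, 0) / (n0 - 1)
  diff <- m1 - m0
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- rep(n1 + n0 - 2, length(diff))
  } else {
    se <- sqrt(v1 / n1 + v0 / n0)
    df <- (v1 / n1 + v0 / n0)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  }
  t_stat <- ifelse(se == 0, ifelse(diff == 0, 0, sign(diff) * Inf),
                   diff / se)
  p <- ifelse(is.finite(t_stat), 2 * stats::pt(-abs(t_stat), df),
              ifelse(t_stat == 0, 1, 0))
  p[se == 0 & diff == 0] <- 1
  data.frame(gene_id = gene_ids(x), t_statistic = t_stat,
             log_ratio = diff, p_value = p, stringsAsFactors = FALSE)
}

#' Build a subtype signature from per-gene statistics
#'
#' Keeps up-regulated genes (`log_ratio > 0`) passing the raw p-value
#' threshold, sorts by descending log ratio (ties by gene ID), and
#' truncates to `max_genes`. With `direction = "abs"` the up-regulation
#' requirement is dropped and ranking is by `|log_ratio|`.
#'
#' @param stats data.frame from [ovr_t_test()].
#' @param subtype subtype index the signature belongs to.
#' @param p_threshold raw p-value gate (default 0.001).
#' @param max_genes signature size cap (default 200).
#' @param direction `"up"` (default) or `"abs"`.
#' @return list of class `subtype_signature` with fields `subtype`,
#'   `genes` (data.frame of retained GeneStat rows in rank order),
#'   `p_threshold`, `max_genes`.
#' @export
build_signature <- function(stats, subtype = NA_integer_,
                            p_threshold = 0.001, max_genes = 200,
                            direction = c("up", "abs")) {
  direction <- match.arg(direction)
  if (nrow(stats) == 0L) stop("`stats` must be nonempty")
  keep <- stats$p_value < p_threshold
  if (direction == "up") {
    keep <- keep & stats$log_ratio > 0
    key <- stats$log_ratio
  } else {
    key <- abs(stats$log_ratio)
  }
  sel <- stats[keep, , drop = FALSE]
  sel <- sel[order(-key[keep], sel$gene_id), , drop = FALSE]
  sel <- utils::head(sel, max_genes)
  rownames(sel) <- NULL
  if (nrow(sel) == 0L)
    warning("empty signature: no gene passed p < ", p_threshold,
            " for subtype ", subtype)
  structure(list(subtype = subtype, genes = sel,
                 p_threshold = p_threshold, max_genes = max_genes),
            class = "subtype_signature")
}

#' @export
print.subtype_signature <- function(x, ...) {
  cat(sprintf("<subtype_signature> subtype %s: %d genes (p < %g, cap %d)\n",
              x$subtype, nrow(x$genes), x$p_threshold, x$max_genes))
  invisible(x)
}

#' One signature per subtype
#'
#' Runs the one-vs-rest contrast and signature selection for every
#' subtype present in `labels`. A gene may legitimately appear in more
#' than one subtype's signature; no exclusivity is enforced.
#'
#' @inheritParams ovr_t_test
#' @inheritParams build_signature
#' @return list of `subtype_signature`, indexed by subtype 1..K.
#' @export
build_all_signatures <- function(x, labels, p_threshold = 0.001,
                                 max_genes = 200, var_equal = TRUE,
                                 direction = "up") {
  subtypes <- sort(unique(labels[sample_ids(x)]))
  lapply(subtypes, function(s) {
    build_signature(ovr_t_test(x, labels, s, var_equal = var_equal),
                    subtype = s, p_threshold = p_threshold,
                    max_genes = max_genes, direction = direction)
  })
}

#' Write signatures as a GMT gene-set file
#'
#' One line per signature: set name, description, then tab-separated
#' gene IDs in rank order -- the standard gene-set exchange format.
#'
#' @param signatures list of `subtype_signature`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(signatures, path) {
  lines <- vapply(signatures, function(sig) {
    paste(c(sprintf("SUBTYPE_%s_UP", sig$subtype),
            sprintf("lncsubtype %s one-vs-rest signature (p<%g, top %d)",
                    pkg_version(), sig$p_threshold, sig$max_genes),
            sig$genes$gene_id), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' @param path GMT file path.
#' @return named list of character gene-ID vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1),
    USE.NAMES = FALSE)
  out
}

#' Write per-gene signature statistics as CSV
#'
#' @param signatures list of `subtype_signature`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature_stats <- function(signatures, path) {
  tab <- do.call(rbind, lapply(signatures, function(sig) {
    if (nrow(sig$genes) == 0L) return(NULL)
    cbind(subtype = sig$subtype, sig$genes, rank = seq_len(nrow(sig$genes)))
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# lncsubtype %s signature statistics", pkg_version()),
             con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}
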