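#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit survival estimate over the distinct event
#' times of a censored sample. Ties are handled the standard way: all
#' events at a tied time are processed simultaneously, and censored
#' observations at the same time are removed from the risk set after
#' the events.
#'
#' @param records data.frame with numeric `time` (> 0) and 0/1 `event`
#'   columns (the layout written by [generate_survival()]).
#' @return data.frame of class `km_curve` with columns `time` (distinct
#'   event times, increasing), `n_risk`, `n_event`, `survival`.
#' @export
km_estimate <- function(records) {
  check_records(records)
  time <- records$time; event <- records$event
  et <- sort(unique(time[event == 1]))
  if (length(et) == 0L) {
    out <- data.frame(time = numeric(0), n_risk = integer(0),
                      n_event = integer(0), survival = numeric(0))
    class(out) <- c("km_curve", "data.frame")
    return(out)
  }
  n_risk <- vapply(et, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(et, function(t) sum(time == t & event == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  out <- data.frame(time = et, n_risk = n_risk, n_event = n_event,
                    survival = surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

check_records <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("`records` must be a nonempty data.frame")
  if (!all(c("time", "event") %in% colnames(records)))
    stop("`records` needs `time` and `event` columns")
  if (any(records$time <= 0)) stop("all times must be > 0")
  if (!all(records$event %in% c(0, 1))) stop("`event` must be 0/1")
  invisible(records)
}

# observed and expected events per group plus the hypergeometric
# variance-covariance matrix, summed over pooled event times
logrank_components <- function(groups) {
  k <- length(groups)
  time <- unlist(lapply(groups, `[[`, "time"), use.names = FALSE)
  event <- unlist(lapply(groups, `[[`, "event"), use.names = FALSE)
  grp <- rep(seq_len(k), vapply(groups, nrow, integer(1)))
  et <- sort(unique(time[event == 1]))
  if (length(et) == 0L)
    stop("log-rank statistic undefined: no events in any group")
  O <- numeric(k); E <- numeric(k); V <- matrix(0, k, k)
  for (t in et) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    d_t <- sum(time == t & event == 1)
    n_kt <- vapply(seq_len(k), function(g) sum(at_risk & grp == g),
                   numeric(1))
    d_kt <- vapply(seq_len(k), function(g)
      sum(time == t & event == 1 & grp == g), numeric(1))
    O <- O + d_kt
    E <- E + d_t * n_kt / n_t
    if (n_t > 1) {
      c_t <- d_t * (n_t - d_t) / (n_t - 1)
      p <- n_kt / n_t
      V <- V + c_t * (diag(p, k) - tcrossprod(p))
    }
  }
  list(O = O, E = E, V = V)
}

#' K-sample log-rank test
#'
#' The standard log-rank statistic: observed-minus-expected events per
#' group accumulated over pooled event times, with the hypergeometric
#' variance-covariance matrix; the quadratic form over any K-1 groups
#' is chi-square with K-1 degrees of freedom under the null.
#'
#' @param groups list (length >= 2) of survival record data.frames, one
#'   per group.
#' @return list with `chi_square`, `df`, `p`, and the per-group
#'   `observed` / `expected` event counts.
#' @export
logrank_global <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  for (g in groups) check_records(g)
  k <- length(groups)
  comp <- logrank_components(groups)
  z <- (comp$O - comp$E)[-k]
  Vr <- comp$V[-k, -k, drop = FALSE]
  stat <- tryCatch(
    as.numeric(z %*% solve(Vr, z)),
    error = function(e) as.numeric(z %*% MASS::ginv(Vr) %*% z)
  )
  df <- k - 1
  list(chi_square = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       observed = comp$O, expected = comp$E)
}

#' All pairwise log-rank comparisons with multiplicity adjustment
#'
#' Runs [logrank_global()] on every pair of groups and adjusts the raw
#' p-values over the family of K(K-1)/2 pairs with Benjamini-Hochberg
#' (default) or Bonferroni. Pairs whose statistic is undefined (e.g. no
#' events) are reported with NA rather than aborting the family.
#'
#' @param groups named list of survival record data.frames.
#' @param adjust `"BH"` (default) or `"bonferroni"`.
#' @return data.frame with `group1`, `group2`, `chi_square`, `raw_p`,
#'   `adjusted_p`.
#' @export
pairwise_logrank <- function(groups, adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (length(groups) < 2) stop("need at least 2 groups")
  nm <- names(groups)
  if (is.null(nm)) nm <- as.character(seq_along(groups))
  pairs <- utils::combn(seq_along(groups), 2)
  res <- apply(pairs, 2, function(idx) {
    r <- tryCatch(logrank_global(groups[idx]),
                  error = function(e) list(chi_square = NA_real_,
                                           p = NA_real_))
    c(chi_square = r$chi_square, raw_p = r$p)
  })
  out <- data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
                    chi_square = res["chi_square", ],
                    raw_p = res["raw_p", ], stringsAsFactors = FALSE)
  out$adjusted_p <- stats::p.adjust(out$raw_p, method = adjust)
  out
}

#' Within-subtype treatment benefit
#'
#' Restricts the records to one subtype, splits them by treatment arm,
#' and returns the two Kaplan-Meier curves with the two-arm log-rank
#' comparison. Callers filter the records to the analysis population
#' (e.g. a stage range) before calling; the endpoint is likewise a
#' pre-filter on records, not a separate code path.
#'
#' @param records survival record data.frame including an `arm` column.
#' @param assignments data.frame with `sample_id` and `hard_label`
#'   columns (e.g. from [predict_subtypes()]).
#' @param subtype the subtype whose arms are compared.
#' @return list with `km_treated`, `km_untreated`, `logrank`, and the
#'   per-arm sample sizes.
#' @export
treatment_benefit <- function(records, assignments, subtype) {
  check_records(records)
  ids <- assignments$sample_id[assignments$hard_label == subtype]
  sub <- records[records$sample_id %in% ids, , drop = FALSE]
  treated <- sub[sub$arm == "treated", , drop = FALSE]
  untreated <- sub[sub$arm == "untreated", , drop = FALSE]
  if (nrow(treated) == 0L || nrow(untreated) == 0L)
    stop("subtype ", subtype, " has an empty treatment arm")
  list(km_treated = km_estimate(treated),
       km_untreated = km_estimate(untreated),
       logrank = logrank_global(list(treated, untreated)),
       n_treated = nrow(treated), n_untreated = nrow(untreated))
}
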