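#' Synthetic cohort configuration
#'
#' Describes a training cohort with `k_subtypes` latent expression
#' subtypes expressed in both a lncRNA and an mRNA feature space. Each
#' subtype owns a disjoint block of marker genes per feature space; a
#' sample's markers are shifted up by `effect_size` log2 units on top of
#' gene baselines, and every gene carries additive Gaussian noise with
#' within-subtype SD `noise_sd`. Defaults are the cohort conditions used
#' throughout the package's own validation: n = 300 samples, six
#' equiprobable subtypes, 50 markers per subtype per space, a 2 log2-unit
#' marker shift over 0.5 log2-unit noise (a 4x effect-to-noise ratio),
#' and a 1 log2-unit per-gene batch shift for derived test cohorts.
#'
#' @param n_samples number of samples.
#' @param n_lnc_genes,n_mrna_genes genes per feature space.
#' @param k_subtypes number of latent subtypes.
#' @param subtype_proportions simplex vector of length `k_subtypes`.
#' @param n_marker_genes_per_subtype markers per subtype in each space.
#' @param effect_size mean up-shift (log2 units) of a subtype's markers.
#' @param noise_sd within-subtype SD (log2 units), > 0.
#' @param batch_shift_sd SD of the per-gene additive shift applied to
#'   test cohorts (log2 units).
#' @param seed integer RNG seed.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 300, n_lnc_genes = 1200,
                          n_mrna_genes = 2500, k_subtypes = 6,
                          subtype_proportions = rep(1 / k_subtypes, k_subtypes),
                          n_marker_genes_per_subtype = 50,
                          effect_size = 2, noise_sd = 0.5,
                          batch_shift_sd = 1, seed = 1L) {
  cfg <- list(n_samples = n_samples, n_lnc_genes = n_lnc_genes,
              n_mrna_genes = n_mrna_genes, k_subtypes = k_subtypes,
              subtype_proportions = subtype_proportions,
              n_marker_genes_per_subtype = n_marker_genes_per_subtype,
              effect_size = effect_size, noise_sd = noise_sd,
              batch_shift_sd = batch_shift_sd, seed = as.integer(seed))
  counts <- c("n_samples", "n_lnc_genes", "n_mrna_genes", "k_subtypes",
              "n_marker_genes_per_subtype")
  for (f in counts)
    if (length(cfg[[f]]) != 1L || cfg[[f]] < 1)
      stop("`", f, "` must be a positive count")
  if (length(cfg$subtype_proportions) != cfg$k_subtypes)
    stop("`subtype_proportions` must have length k_subtypes")
  if (abs(sum(cfg$subtype_proportions) - 1) > 1e-9)
    stop("`subtype_proportions` must sum to 1")
  if (cfg$noise_sd <= 0) stop("`noise_sd` must be > 0")
  if (cfg$batch_shift_sd < 0) stop("`batch_shift_sd` must be >= 0")
  needed <- cfg$k_subtypes * cfg$n_marker_genes_per_subtype
  if (needed > cfg$n_lnc_genes || needed > cfg$n_mrna_genes)
    stop("marker genes per subtype x k_subtypes exceeds the gene count ",
         "in one feature space")
  structure(cfg, class = "cohort_config")
}

#' Generate a training cohort with latent subtypes
#'
#' Draws subtype labels from `subtype_proportions`, then builds paired
#' lncRNA and mRNA matrices sharing those samples. Per feature space,
#' subtype `s` owns the `s`-th block of `n_marker_genes_per_subtype`
#' gene rows; those rows are shifted by `+effect_size` in samples of
#' subtype `s`. Gene baselines are N(6, 1.5) log2 units and all cells
#' get N(0, noise_sd^2) noise. True labels are returned for oracle use
#' only -- the pipeline itself never sees them.
#'
#' @param config a [cohort_config()].
#' @return list with `lnc` and `mrna` (`expr_matrix`), `labels` (named
#'   integer vector in 1..K), and `marker_genes` (per-space list of
#'   per-subtype marker ID vectors).
#' @export
generate_training_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_samples
  k <- config$k_subtypes
  sid <- sprintf("S%04d", seq_len(n))
  labels <- sample.int(k, n, replace = TRUE, prob = config$subtype_proportions)
  names(labels) <- sid

  build_space <- function(n_genes, prefix) {
    gid <- sprintf("%s%05d", prefix, seq_len(n_genes))
    baseline <- stats::rnorm(n_genes, mean = 6, sd = 1.5)
    vals <- baseline + matrix(stats::rnorm(n_genes * n, sd = config$noise_sd),
                              nrow = n_genes)
    m <- config$n_marker_genes_per_subtype
    markers <- vector("list", k)
    for (s in seq_len(k)) {
      rows <- ((s - 1L) * m + 1L):(s * m)
      markers[[s]] <- gid[rows]
      vals[rows, labels == s] <- vals[rows, labels == s] + config$effect_size
    }
    dimnames(vals) <- list(gid, sid)
    list(values = vals, markers = markers)
  }

  lnc <- build_space(config$n_lnc_genes, "LNC")
  mrna <- build_space(config$n_mrna_genes, "MRNA")
  list(
    lnc = expression_matrix(lnc$values, "lncRNA", "synthetic-train"),
    mrna = expression_matrix(mrna$values, "mRNA", "synthetic-train"),
    labels = labels,
    marker_genes = list(lnc = lnc$markers, mrna = mrna$markers)
  )
}

#' Apply a per-gene additive batch shift
#'
#' Emulates a platform change: one offset per gene is drawn from
#' N(0, batch_shift_sd^2) and added to every sample, leaving gene and
#' sample IDs untouched. Per-gene z-scoring within the shifted cohort
#' absorbs the offsets exactly, which is what the cross-cohort
#' prediction contract relies on.
#'
#' @param x an `expr_matrix`.
#' @param batch_shift_sd SD of the per-gene offsets, >= 0.
#' @param seed integer RNG seed.
#' @param cohort_tag tag for the shifted cohort.
#' @return an `expr_matrix` of identical shape.
#' @export
apply_batch_shift <- function(x, batch_shift_sd, seed,
                              cohort_tag = paste0(x$cohort_tag, "-shifted")) {
  stopifnot(is_expr_matrix(x))
  if (batch_shift_sd < 0) stop("`batch_shift_sd` must be >= 0")
  set.seed(as.integer(seed))
  offsets <- stats::rnorm(nrow(x$values), sd = batch_shift_sd)
  x$values <- x$values + offsets
  x$cohort_tag <- cohort_tag
  x
}

#' Survival-generator configuration
#'
#' Per-subtype exponential event hazards (events/month), per-subtype
#' treatment hazard ratios applied multiplicatively within the treated
#' arm, an independent exponential censoring rate, and administrative
#' censoring at `max_followup` months. Defaults give six subtypes with
#' median event times from ~8 to ~70 months, a strong chemotherapy
#' benefit in subtype 2 and none in subtypes 3 and 6 -- the qualitative
#' structure of subtype-dependent prognosis and treatment response.
#'
#' @param baseline_hazard_per_subtype events/month, length K, all > 0.
#' @param treatment_hazard_ratio_per_subtype multiplicative arm effect
#'   within subtype, length K, all > 0.
#' @param censoring_rate exponential censoring events/month, >= 0.
#' @param max_followup administrative censoring time, months.
#' @return list of class `survival_config`.
#' @export
survival_config <- function(
    baseline_hazard_per_subtype = c(0.08, 0.04, 0.015, 0.035, 0.01, 0.09),
    treatment_hazard_ratio_per_subtype = c(0.8, 0.4, 1.0, 0.7, 0.9, 1.0),
    censoring_rate = 0.01, max_followup = 120) {
  if (any(baseline_hazard_per_subtype <= 0))
    stop("all baseline hazards must be > 0")
  if (any(treatment_hazard_ratio_per_subtype <= 0))
    stop("all treatment hazard ratios must be > 0")
  if (length(baseline_hazard_per_subtype) !=
      length(treatment_hazard_ratio_per_subtype))
    stop("hazard and hazard-ratio vectors must share length K")
  if (censoring_rate < 0) stop("`censoring_rate` must be >= 0")
  if (max_followup <= 0) stop("`max_followup` must be > 0")
  structure(list(
    baseline_hazard_per_subtype = baseline_hazard_per_subtype,
    treatment_hazard_ratio_per_subtype = treatment_hazard_ratio_per_subtype,
    censoring_rate = censoring_rate, max_followup = max_followup
  ), class = "survival_config")
}

#' Generate censored survival records for labeled samples
#'
#' Event times are exponential with rate
#' `baseline_hazard[label] * (treatment_hazard_ratio[label] if treated)`;
#' censoring times are exponential with `censoring_rate`; the observed
#' time is the minimum of event, censoring and `max_followup`, with the
#' event indicator set accordingly.
#'
#' @param labels named integer vector of subtype labels (1..K).
#' @param arms character vector, `"treated"`/`"untreated"`/`"unknown"`,
#'   one per sample (recycled if length 1).
#' @param config a [survival_config()].
#' @param seed integer RNG seed.
#' @param endpoint `"OS"` or `"RFS"`.
#' @return data.frame with columns `sample_id`, `time`, `event`,
#'   `endpoint`, `arm`, `stage` (NA).
#' @export
generate_survival <- function(labels, arms = "unknown", config, seed,
                              endpoint = c("OS", "RFS")) {
  stopifnot(inherits(config, "survival_config"))
  endpoint <- match.arg(endpoint)
  k <- length(config$baseline_hazard_per_subtype)
  if (any(labels < 1 | labels > k))
    stop("unknown label index: labels must lie in 1..", k)
  n <- length(labels)
  arms <- rep_len(arms, n)
  set.seed(as.integer(seed))
  rate <- config$baseline_hazard_per_subtype[labels]
  treated <- arms == "treated"
  rate[treated] <- rate[treated] *
    config$treatment_hazard_ratio_per_subtype[labels[treated]]
  t_event <- stats::rexp(n, rate)
  t_cens <- if (config$censoring_rate > 0)
    stats::rexp(n, config$censoring_rate) else rep(Inf, n)
  time <- pmin(t_event, t_cens, config$max_followup)
  data.frame(
    sample_id = if (is.null(names(labels))) as.character(seq_len(n))
                else names(labels),
    time = time,
    event = as.integer(t_event <= t_cens & t_event <= config$max_followup),
    endpoint = endpoint, arm = arms, stage = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Drug-panel configuration
#'
#' A cell-line panel whose drug response AUC (area under the
#' dose-response curve; higher = more resistant) is, for a chosen subset
#' of drugs, linearly coupled to each line's subtype-membership
#' probability with slope `coupling_slope` (negative for drugs that
#' preferentially kill high-probability lines). Defaults plant 3 coupled
#' drugs among 20 on a 40-line panel with slope -5 AUC units per unit
#' probability over unit noise.
#'
#' @param n_cell_lines,n_drugs panel dimensions.
#' @param coupled_drug_indices which drugs are coupled (subset of
#'   `1:n_drugs`).
#' @param coupling_slope AUC units per unit probability.
#' @param auc_noise_sd residual AUC noise SD.
#' @return list of class `drug_panel_config`.
#' @export
drug_panel_config <- function(n_cell_lines = 40, n_drugs = 20,
                              coupled_drug_indices = 1:3,
                              coupling_slope = -5, auc_noise_sd = 1) {
  if (n_cell_lines < 1 || n_drugs < 1) stop("panel dimensions must be positive")
  if (length(coupled_drug_indices) &&
      (any(coupled_drug_indices < 1) || any(coupled_drug_indices > n_drugs)))
    stop("`coupled_drug_indices` must be a subset of 1..n_drugs")
  if (auc_noise_sd < 0) stop("`auc_noise_sd` must be >= 0")
  structure(list(n_cell_lines = n_cell_lines, n_drugs = n_drugs,
                 coupled_drug_indices = as.integer(coupled_drug_indices),
                 coupling_slope = coupling_slope,
                 auc_noise_sd = auc_noise_sd),
            class = "drug_panel_config")
}

#' Generate a drug-by-cell-line AUC panel
#'
#' Coupled drugs: `AUC = 10 + coupling_slope * probability + noise`;
#' uncoupled drugs: `AUC = 10 + noise`. The intercept of 10 AUC units is
#' fixed -- only slopes and noise matter to rank-based screening. Two
#' independent panels (e.g. two pharmacogenomic datasets) are obtained
#' with distinct seeds.
#'
#' @param cell_line_probabilities numeric in \[0,1\], one per line,
#'   optionally named with cell-line IDs.
#' @param config a [drug_panel_config()].
#' @param seed integer RNG seed.
#' @return numeric matrix, drugs x cell lines, with drug rownames
#'   `DRUG01..` and cell-line colnames.
#' @export
generate_drug_panel <- function(cell_line_probabilities, config, seed) {
  stopifnot(inherits(config, "drug_panel_config"))
  p <- cell_line_probabilities
  if (length(p) != config$n_cell_lines)
    stop("need one probability per cell line")
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  set.seed(as.integer(seed))
  nl <- config$n_cell_lines
  nd <- config$n_drugs
  auc <- matrix(10 + stats::rnorm(nd * nl, sd = config$auc_noise_sd),
                nrow = nd)
  for (d in config$coupled_drug_indices)
    auc[d, ] <- auc[d, ] + config$coupling_slope * p
  rownames(auc) <- sprintf("DRUG%02d", seq_len(nd))
  colnames(auc) <- if (!is.null(names(p))) names(p)
                   else sprintf("CL%03d", seq_len(nl))
  auc
}
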