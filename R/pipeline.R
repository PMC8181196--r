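#' Pipeline configuration
#'
#' Collects every stage's parameters with the package defaults: the
#' synthetic cohort (see [cohort_config()]), clustering (correlation
#' distance, average linkage, top 1000 variable genes, K = 6),
#' signature selection (p < 0.001, top 200 by log ratio), BCCP priors
#' (0.5 per subtype, shared variance), survival analysis (OS endpoint,
#' BH pairwise adjustment) and association screening (alpha = 0.05,
#' 1000 GSEA permutations). All values can be overridden by name.
#'
#' @param seed global RNG seed; stage seeds are derived from it.
#' @param out_dir output directory for [run_full()].
#' @param ... overrides for any default field.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = "results", ...) {
  cfg <- list(
    seed = as.integer(seed), out_dir = out_dir,
    cohort = list(n_samples = 300, n_lnc_genes = 1200, n_mrna_genes = 2500,
                  k_subtypes = 6, n_marker_genes_per_subtype = 50,
                  effect_size = 2, noise_sd = 0.5, batch_shift_sd = 1),
    clustering = list(k = 6, n_top = 1000, distance = "correlation",
                      linkage = "average"),
    signature = list(p_threshold = 0.001, max_genes = 200),
    bccp = list(prior_in = 0.5, shared_variance = TRUE),
    survival = list(endpoint = "OS", adjust = "BH"),
    association = list(alpha = 0.05, n_permutations = 1000)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && nm %in% names(cfg))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
    else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks ranges, simplex constraints and cross-stage K consistency
#' before anything runs; an empty return value means the configuration
#' is valid.
#'
#' @param config a [pipeline_config()].
#' @return character vector of problems (empty when valid).
#' @export
validate_config <- function(config) {
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  co <- config$cohort
  for (f in c("n_samples", "n_lnc_genes", "n_mrna_genes", "k_subtypes",
              "n_marker_genes_per_subtype"))
    if (is.null(co[[f]]) || co[[f]] < 1)
      add(sprintf("cohort$%s must be a positive count", f))
  if (!is.null(co$noise_sd) && co$noise_sd <= 0)
    add("cohort$noise_sd must be > 0")
  if (!is.null(co$batch_shift_sd) && co$batch_shift_sd < 0)
    add("cohort$batch_shift_sd must be >= 0")
  if (!is.null(co$subtype_proportions)) {
    if (length(co$subtype_proportions) != co$k_subtypes)
      add("cohort$subtype_proportions length must equal k_subtypes")
    else if (abs(sum(co$subtype_proportions) - 1) > 1e-9)
      add("cohort$subtype_proportions must sum to 1 (simplex violation)")
  }
  if (!is.null(config$clustering$k) && !is.null(co$k_subtypes) &&
      config$clustering$k != co$k_subtypes)
    add("K mismatch: clustering$k differs from cohort$k_subtypes")
  sg <- config$signature
  if (sg$p_threshold <= 0 || sg$p_threshold >= 1)
    add("signature$p_threshold must lie in (0, 1)")
  if (sg$max_genes < 1) add("signature$max_genes must be positive")
  if (config$bccp$prior_in <= 0 || config$bccp$prior_in >= 1)
    add("bccp$prior_in must lie in (0, 1)")
  if (!config$survival$endpoint %in% c("OS", "RFS"))
    add("survival$endpoint must be OS or RFS")
  if (config$association$alpha <= 0 || config$association$alpha > 1)
    add("association$alpha must lie in (0, 1]")
  if (!is.null(config$input_paths)) {
    missing <- config$input_paths[!file.exists(unlist(config$input_paths))]
    for (p in missing) add(sprintf("input path does not exist: %s", p))
  }
  problems
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes simulate -> discover -> signature -> train -> predict ->
#' survival -> associate with one configuration, writes every artifact
#' under `config$out_dir`, and returns (and writes) a JSON manifest of
#' produced files with their MD5 hashes so a run can be audited and
#' reproduced. The same config and seed give byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (list with parameters and per-file
#'   hashes).
#' @export
run_full <- function(config) {
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  files <- character(0)
  add_file <- function(path) files <<- c(files, path)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    message(sprintf("[%s] running ...", name))
    r <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    r
  }

  co <- config$cohort
  cohort <- stage("simulate", {
    cc <- cohort_config(
      n_samples = co$n_samples, n_lnc_genes = co$n_lnc_genes,
      n_mrna_genes = co$n_mrna_genes, k_subtypes = co$k_subtypes,
      n_marker_genes_per_subtype = co$n_marker_genes_per_subtype,
      effect_size = co$effect_size, noise_sd = co$noise_sd,
      batch_shift_sd = co$batch_shift_sd, seed = seed)
    tc <- generate_training_cohort(cc)
    add_file(write_expression(tc$lnc, file.path(out, "lnc_train.tsv")))
    add_file(write_expression(tc$mrna, file.path(out, "mrna_train.tsv")))
    tc
  })

  clus <- stage("discover", {
    centered <- median_center_genes(cohort$lnc)
    genes <- select_variable_genes(
      centered, min(config$clustering$n_top, nrow(centered$values)))
    hierarchical_cluster(centered, genes, k = config$clustering$k,
                         distance = config$clustering$distance,
                         linkage = config$clustering$linkage)
  })
  lab_path <- file.path(out, "labels.csv")
  utils::write.csv(data.frame(sample_id = names(clus$labels),
                              label = clus$labels, row.names = NULL),
                   lab_path, row.names = FALSE)
  add_file(lab_path)

  sigs <- stage("signature", {
    s <- build_all_signatures(cohort$mrna, clus$labels,
                              p_threshold = config$signature$p_threshold,
                              max_genes = config$signature$max_genes)
    add_file(write_gmt(s, file.path(out, "signatures.gmt")))
    add_file(write_signature_stats(s, file.path(out, "signature_stats.csv")))
    s
  })

  models <- stage("train", {
    train_multiclass(zscore_genes(cohort$mrna), clus$labels, sigs,
                     priors = config$bccp$prior_in,
                     shared_variance = config$bccp$shared_variance)
  })

  pred <- stage("predict", {
    test <- apply_batch_shift(cohort$mrna, co$batch_shift_sd,
                              seed = seed + 1L)
    p <- predict_subtypes(models, zscore_genes(test))
    pp <- file.path(out, "assignments.csv")
    utils::write.csv(p, pp, row.names = FALSE)
    add_file(pp)
    p
  })

  surv <- stage("survival", {
    set.seed(seed + 2L)
    arms <- sample(c("treated", "untreated"), length(clus$labels),
                   replace = TRUE)
    rec <- generate_survival(clus$labels, arms, survival_config(),
                             seed = seed + 3L,
                             endpoint = config$survival$endpoint)
    rp <- file.path(out, "survival.csv")
    utils::write.csv(rec, rp, row.names = FALSE)
    add_file(rp)
    groups <- split(rec, clus$labels[rec$sample_id])
    global <- logrank_global(groups)
    pw <- pairwise_logrank(groups, adjust = config$survival$adjust)
    pwp <- file.path(out, "pairwise_logrank.csv")
    utils::write.csv(pw, pwp, row.names = FALSE)
    add_file(pwp)
    list(global = global, pairwise = pw)
  })

  stage("associate", {
    ct <- cross_tabulate(clus$labels, cohort$labels)
    cp <- file.path(out, "crosstab_vs_truth.csv")
    utils::write.csv(as.data.frame.matrix(ct), cp)
    add_file(cp)
    ct
  })

  manifest <- list(
    package = "lncsubtype", version = pkg_version(),
    seed = seed, parameters = unclass(config)[setdiff(names(config),
                                                      c("seed", "out_dir"))],
    global_logrank_p = surv$global$p,
    files = lapply(stats::setNames(files, basename(files)), function(f)
      list(path = f, md5 = unname(tools::md5sum(f))))
  )
  mp <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  message("manifest written to ", mp)
  invisible(manifest)
}
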