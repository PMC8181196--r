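# Small cohorts used across tests: fast to generate, same structure as
# the full-size defaults.

small_cohort <- function(seed = 1L, k = 3L, n = 60L, effect = 2,
                         noise = 0.5, n_lnc = 150L, n_mrna = 300L,
                         markers = 15L) {
  generate_training_cohort(cohort_config(
    n_samples = n, n_lnc_genes = n_lnc, n_mrna_genes = n_mrna,
    k_subtypes = k, n_marker_genes_per_subtype = markers,
    effect_size = effect, noise_sd = noise, seed = seed))
}

# a bare expr_matrix from a plain matrix, generating IDs when absent
em <- function(values, feature_space = "mRNA", tag = "toy") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("G%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%03d", seq_len(ncol(values)))
  expression_matrix(values, feature_space, tag)
}
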