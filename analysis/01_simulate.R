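#!/usr/bin/env Rscript
# Stage 1 — simulate the study's data structures.
#
# Builds a training cohort (n = 300, six latent subtypes expressed in a
# 1200-gene lncRNA space and a 2500-gene mRNA space), a batch-shifted
# test cohort standing in for an independent platform, per-sample
# survival records with subtype- and arm-dependent hazards, and two
# independent drug panels whose first three drugs are negatively
# coupled to subtype-6 membership probability.

suppressPackageStartupMessages(library(lncsubtype))
seed <- 20260929L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- cohort_config(seed = seed)
cohort <- generate_training_cohort(cfg)
write_expression(cohort$lnc, file.path(out, "lnc_train.tsv"))
write_expression(cohort$mrna, file.path(out, "mrna_train.tsv"))

test_mrna <- apply_batch_shift(cohort$mrna, cfg$batch_shift_sd,
                               seed = seed + 1L, cohort_tag = "synthetic-test")
write_expression(test_mrna, file.path(out, "mrna_test.tsv"))

set.seed(seed + 2L)
arms <- sample(c("treated", "untreated"), cfg$n_samples, replace = TRUE)
surv <- generate_survival(cohort$labels, arms, survival_config(),
                          seed = seed + 3L, endpoint = "OS")
write.csv(cbind(surv, label = cohort$labels[surv$sample_id]),
          file.path(out, "survival.csv"), row.names = FALSE)

write.csv(data.frame(sample_id = names(cohort$labels),
                     true_label = cohort$labels),
          file.path(out, "true_labels.csv"), row.names = FALSE)

# two pharmacogenomic panels: 40 lines each, subtype-6 membership
# probability coupled (slope -5) to drugs 1-3
set.seed(seed + 4L)
panel_cfg <- drug_panel_config()
p1 <- setNames(runif(40), sprintf("LINE_A%02d", 1:40))
p2 <- setNames(runif(40), sprintf("LINE_B%02d", 1:40))
write.csv(data.frame(cell_line = c(names(p1), names(p2)),
                     dataset = rep(c("panelA", "panelB"), each = 40),
                     l6_probability = c(p1, p2)),
          file.path(out, "cell_line_probabilities.csv"), row.names = FALSE)
write.csv(generate_drug_panel(p1, panel_cfg, seed + 5L),
          file.path(out, "drug_auc_panelA.csv"))
write.csv(generate_drug_panel(p2, panel_cfg, seed + 6L),
          file.path(out, "drug_auc_panelB.csv"))

message(sprintf(
  "simulated: %d samples, subtype sizes %s; %d+%d genes; 2 drug panels",
  cfg$n_samples, paste(tabulate(cohort$labels, 6), collapse = "/"),
  cfg$n_lnc_genes, cfg$n_mrna_genes))
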