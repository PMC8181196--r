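#!/usr/bin/env Rscript
# Stage 3 — subtype-specific mRNA signatures.
#
# For each discovered subtype, one-vs-rest pooled-variance t-tests over
# all mRNAs; genes with p < 0.001 and positive log ratio are ranked by
# log ratio and the top 200 kept as that subtype's signature.

suppressPackageStartupMessages(library(lncsubtype))
out <- "results"

mrna <- read_expression("results/data/mrna_train.tsv", "mRNA", "train")
lab <- read.csv(file.path(out, "cluster_labels.csv"))
labels <- setNames(lab$label, lab$sample_id)

sigs <- build_all_signatures(mrna, labels, p_threshold = 0.001,
                             max_genes = 200)
write_gmt(sigs, file.path(out, "signatures.gmt"))
write_signature_stats(sigs, file.path(out, "signature_stats.csv"))

for (s in seq_along(sigs)) {
  g <- sigs[[s]]$genes
  message(sprintf(
    "subtype %d: %3d genes (top log-ratio %.2f, median t = %.1f)",
    s, nrow(g), max(g$log_ratio), median(g$t_statistic)))
}
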