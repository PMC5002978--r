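#!/usr/bin/env Rscript
# Stage 5: promoter-proximal pausing.
#
# Fixes each gene's 50-bp pause window from the pooled NHS track
# (maximal-count window in [-50, +150)), computes pausing indices and
# Fisher's-exact paused calls per condition, and tests for pausing-level
# changes between conditions with the NB machinery at FDR 0.001.

library(proseqhs)
source("analysis/helpers_load.R")

d <- load_simulated("results/simulated")
sf <- read.table("results/size_factors.tsv", header = TRUE, sep = "\t")
classes <- read.table("results/filtered_classes.tsv", header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)

is_nhs <- d$design$condition == "NHS"
pool_nhs <- pool_tracks(d$tracks[is_nhs])
pool_hs <- pool_tracks(d$tracks[!is_nhs])

pt <- pausing_table(pool_nhs, list(NHS = pool_nhs, HS = pool_hs), d$genes)
write.table(pt, "results/pausing.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

pc <- pausing_change_test(pool_nhs, d$tracks, d$genes, sf$size_factor,
                          d$design$condition)
write.table(pc, "results/pausing_change.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cls <- classes$filtered_class[match(pt$gene_id, classes$gene_id)]
cat(sprintf("Paused in NHS: %.1f%% of all genes\n",
            100 * mean(pt$paused_NHS)))
for (cl in c("activated", "repressed", "unchanged")) {
  cat(sprintf("  %s: %.1f%% paused, median PI %.1f\n", cl,
              100 * mean(pt$paused_NHS[cls == cl], na.rm = TRUE),
              median(pt$pi_NHS[cls == cl], na.rm = TRUE)))
}
cat("Genes with significant pausing change (FDR 0.001):",
    sum(pc$padj <= 0.001, na.rm = TRUE), "\n")
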