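#!/usr/bin/env Rscript
# Stage 3: differential transcription.
#
# Counts gene-body reads in the 20-min contrast window [+200,
# min(L, 20 kb)) for every library, runs the NB Wald test with the
# externally derived size factors, adjusts by Benjamini-Hochberg and
# assigns the activated / repressed / unchanged / ambiguous classes at
# FDR 0.001. Scores the calls against the simulation truth table.

library(proseqhs)
source("analysis/helpers_load.R")

d <- load_simulated("results/simulated")
sf <- read.table("results/size_factors.tsv", header = TRUE, sep = "\t")

bc <- body_count_matrix(d$tracks, d$genes, t_minutes = 20)
de <- differential_test(bc$counts, sf$size_factor, d$design$condition)
write.table(de, "results/differential.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- d$truth[match(de$gene_id, d$truth$gene_id), ]
tab <- table(truth = truth$class, called = de$class)
print(tab)
recall_act <- mean(de$class[truth$class == "activated"] == "activated")
recall_rep <- mean(de$class[truth$class == "repressed"] == "repressed")
called <- de$class %in% c("activated", "repressed")
efdr <- sum(called & truth$class == "unchanged" &
              !truth$runthrough_victim) / max(1, sum(called))
cat(sprintf("Recall: activated %.1f%%, repressed %.1f%%\n",
            100 * recall_act, 100 * recall_rep))
cat(sprintf("Empirical FDR (excluding run-through victims): %.2f%%\n",
            100 * efdr))
cat("Run-through victims currently misclassified as activated:",
    sum(truth$runthrough_victim & de$class == "activated"),
    "(handled by stage 04)\n")
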