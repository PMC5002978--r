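#!/usr/bin/env Rscript
# Stage 7: transcription-factor binding statistics.
#
# For the simulated HSF-style peak set: closest peak-to-TSS distance per
# gene, bound calls within +/-1 kb, a KS comparison of the distance
# distributions of activated vs unchanged genes, and a Mann-Whitney
# enrichment screen of promoter signal between the classes.

library(proseqhs)
source("analysis/helpers_load.R")

d <- load_simulated("results/simulated")
classes <- read.table("results/filtered_classes.tsv", header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
cls <- setNames(classes$filtered_class, classes$gene_id)
act <- names(cls)[cls == "activated" & !is.na(cls)]
unch <- names(cls)[cls == "unchanged" & !is.na(cls)]

peaks <- d$peaks$hsf
dist <- peak_distance_table(peaks, d$genes)
write.table(dist, "results/peak_distances.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
bound <- bound_genes(peaks, d$genes, max_dist = 1000)
cat(sprintf("Bound genes (peak within 1 kb of TSS): %d of %d\n",
            length(bound), nrow(d$genes)))
cat(sprintf("  activated: %.1f%% bound; unchanged: %.1f%% bound\n",
            100 * mean(act %in% bound), 100 * mean(unch %in% bound)))

ks <- distance_cdf_compare(dist$distance[dist$gene_id %in% act],
                           dist$distance[dist$gene_id %in% unch])
cat(sprintf("KS test activated vs unchanged distances: D = %.3f, p = %.3g\n",
            ks$D, ks$p))

# enrichment screen on promoter signal ([-750, +750) reads, NHS)
is_nhs <- d$design$condition == "NHS"
pool_nhs <- pool_tracks(d$tracks[is_nhs])
sig <- cbind(proseq_promoter = promoter_signal(pool_nhs, d$genes))
scr <- enrichment_screen(sig, act, unch)
write.table(scr, "results/enrichment_screen.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(scr)
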