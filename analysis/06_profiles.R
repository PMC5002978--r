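#!/usr/bin/env Rscript
# Stage 6: composite metagene profiles and heat-map matrices.
#
# Bins sense-strand signal around the TSS (-100..+200 bp, 5-bp bins) per
# condition, builds per-class composites as the median of 1000 subsample
# means (10% of genes each) with a 75% confidence band, and writes a
# pause-distance-ordered heat-map matrix.

library(proseqhs)
source("analysis/helpers_load.R")

d <- load_simulated("results/simulated")
classes <- read.table("results/filtered_classes.tsv", header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
sf <- read.table("results/size_factors.tsv", header = TRUE, sep = "\t")

is_nhs <- d$design$condition == "NHS"
cls <- setNames(classes$filtered_class, classes$gene_id)

for (cond in c("NHS", "HS")) {
  pool <- pool_tracks(d$tracks[if (cond == "NHS") is_nhs else !is_nhs])
  bp <- bin_profile(pool, d$genes, extent = c(-100, 200), bin_size = 5)
  for (cl in c("activated", "repressed", "unchanged")) {
    ids <- names(cls)[cls == cl & !is.na(cls)]
    ids <- setdiff(ids, rownames(bp$matrix)[bp$flagged])
    if (length(ids) < 10) next
    cp <- composite_profile(bp$matrix[ids, , drop = FALSE],
                            n_subsamples = 1000, fraction = 0.1,
                            ci = 0.75, seed = 1)
    cp$bin_center <- bp$bin_centers
    write.table(cp, sprintf("results/composite_%s_%s.tsv", cl, cond),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cat(sprintf("%s / %s: %d genes, peak median %.2f at %g bp\n", cond,
                cl, length(ids), max(cp$median),
                bp$bin_centers[which.max(cp$median)]))
  }
}

# heat map of NHS signal ordered by pause-peak distance to the TSS
pool_nhs <- pool_tracks(d$tracks[is_nhs])
bp <- bin_profile(pool_nhs, d$genes, extent = c(-100, 200), bin_size = 5)
hm <- heatmap_matrix(bp$matrix[!bp$flagged, , drop = FALSE],
                     "distance_to_max_bin", bin_centers = bp$bin_centers)
write.table(cbind(hm$order_key,
                  as.data.frame(hm$matrix, check.names = FALSE)),
            "results/heatmap_nhs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Heat-map matrix:", nrow(hm$matrix), "genes ordered by pause distance\n")
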