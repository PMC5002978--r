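#!/usr/bin/env Rscript
# Stage 2: invariant gene set + size factors.
#
# Reads the simulated libraries back from their bedGraph files, selects
# the invariant ("unchanged") gene set - antisense fraction <= 0.2 in
# both conditions, ChIP z-score > 3, fold change inside 0.85-1.15 - and
# derives between-library normalization factors from the summed gene-body
# reads of that set.

library(proseqhs)

in_dir <- "results/simulated"
dir.create("results", showWarnings = FALSE)

man <- read.table(file.path(in_dir, "manifest.tsv"), header = TRUE,
                  sep = "\t", stringsAsFactors = FALSE)
design <- read.table(file.path(in_dir, "design.tsv"), header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)
genes <- read_genes(man$path[man$type == "genes"])
chip <- read.table(file.path(in_dir, "chip_signal.tsv"), header = TRUE,
                   sep = "\t")
chip <- chip$chip_signal[match(genes$gene_id, chip$gene_id)]

tracks <- lapply(seq_len(nrow(design)), function(i) {
  base <- sprintf("lib%d_%s", design$library_index[i], design$condition[i])
  read_bedgraph_pair(
    man$path[man$type == "bedgraph_plus" & man$name == base],
    man$path[man$type == "bedgraph_minus" & man$name == base])
})
names(tracks) <- paste0("lib", design$library_index)
is_nhs <- design$condition == "NHS"

sel <- select_unchanged_genes(tracks[is_nhs], tracks[!is_nhs], genes, chip)
sf <- compute_size_factors(tracks, genes, sel$unchanged)

write.table(sel$audit, "results/normalization_audit.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(library = names(sf$size_factors),
                       size_factor = sf$size_factors,
                       reference_sum = sf$reference_sums),
            "results/size_factors.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Invariant set:", length(sel$unchanged), "of", nrow(genes),
    "genes pass all three filters\n")
cat("Size factors:", paste(names(sf$size_factors),
                           round(sf$size_factors, 4)), "\n")
cat("True depth factors (for reference): ",
    paste(design$scale_factor), "\n")
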