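#!/usr/bin/env Rscript
# Stage 1: simulate the study dataset.
#
# Builds the default synthetic scenario - 2000 genes on 2 chromosomes,
# 5% activated at 8-fold, 15% repressed at 3-fold, 1% run-through victims
# downstream of activated sources - and four PRO-seq libraries (two NHS,
# two at 20 min of heat shock) with depth factors 1.0, 1.3, 0.8, 1.1.
# Writes the bedGraph/BED/TSV fixture files plus an HSF-style peak set so
# later stages can run purely from files.

library(proseqhs)

out_dir <- "results/simulated"
seed <- 1

cfg <- scenario_config(runthrough_frac = 0.01, seed = seed)
sc <- generate_scenario(cfg)
ex <- simulate_experiment(sc)
peaks <- simulate_peaks(sc, target_classes = "activated")

man <- emit_fixture_files(sc, ex, out_dir, peaks = list(hsf = peaks))
write.table(man, file.path(out_dir, "manifest.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
# ChIP signal used by the normalization stage
write.table(sc$truth[, c("gene_id", "chip_signal")],
            file.path(out_dir, "chip_signal.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Simulated", nrow(sc$genes), "genes;",
    sum(sc$truth$class == "activated"), "activated,",
    sum(sc$truth$class == "repressed"), "repressed,",
    sum(sc$truth$runthrough_victim), "run-through victims.\n")
cat("Library depths:",
    paste(round(sapply(ex$tracks, track_total) / 1e6, 2), "M reads"), "\n")
cat("Files in", out_dir, "\n")
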