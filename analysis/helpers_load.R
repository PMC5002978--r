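# Shared loader for the analysis stages: reads the simulated fixture
# files back into tracks, genes, truth and design.
load_simulated <- function(in_dir) {
  man <- read.table(file.path(in_dir, "manifest.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
  design <- read.table(file.path(in_dir, "design.tsv"), header = TRUE,
                       sep = "\t", stringsAsFactors = FALSE)
  genes <- read_genes(man$path[man$type == "genes"])
  truth <- read.table(man$path[man$type == "truth"], header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
  tracks <- lapply(seq_len(nrow(design)), function(i) {
    base <- sprintf("lib%d_%s", design$library_index[i],
                    design$condition[i])
    read_bedgraph_pair(
      man$path[man$type == "bedgraph_plus" & man$name == base],
      man$path[man$type == "bedgraph_minus" & man$name == base])
  })
  names(tracks) <- paste0("lib", design$library_index)
  peaks <- lapply(man$path[man$type == "peaks"], read_intervals)
  names(peaks) <- man$name[man$type == "peaks"]
  list(manifest = man, design = design, genes = genes, truth = truth,
       tracks = tracks, peaks = peaks)
}
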