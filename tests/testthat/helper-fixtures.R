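# Shared fixture builders: tiny tracks and gene tables constructed in code.

# track from relative offsets for a single gene: offsets are in
# transcription direction, counts default 1
rel_track <- function(gene, offsets, counts = NULL, strand = NULL,
                      chrom_sizes = NULL) {
  if (is.null(strand)) strand <- gene$strand
  if (is.null(counts)) counts <- rep(1, length(offsets))
  dirn <- if (gene$strand == "+") 1L else -1L
  pos <- gene$tss + dirn * offsets
  signal_track(rep(gene$chrom, length(pos)), rep(strand, length(pos)),
               pos, counts, chrom_sizes = chrom_sizes)
}

one_gene <- function(strand = "+", start = 10000, end = 15000,
                     chrom = "chr1", id = "gA") {
  gene_table(id, chrom, start, end, strand)[1, ]
}

# reflect a track through the chromosome midpoint and flip strands
mirror_track <- function(track, chrom_sizes) {
  dt <- track$data
  signal_track(dt$chrom,
               ifelse(dt$strand == "+", "-", "+"),
               chrom_sizes[dt$chrom] - 1L - dt$pos,
               dt$count, chrom_sizes = chrom_sizes)
}

mirror_genes <- function(genes, chrom_sizes) {
  gene_table(genes$gene_id, genes$chrom,
             chrom_sizes[genes$chrom] - genes$end,
             chrom_sizes[genes$chrom] - genes$start,
             ifelse(genes$strand == "+", "-", "+"))
}

# random sparse track on one chromosome/strand pair for property tests
random_track <- function(n_pos = 50, chrom_len = 10000, seed = 1) {
  set.seed(seed)
  pos <- sample.int(chrom_len, n_pos) - 1L
  strand <- sample(c("+", "-"), n_pos, replace = TRUE)
  signal_track(rep("chr1", n_pos), strand, pos,
               sample(1:5, n_pos, replace = TRUE),
               chrom_sizes = c(chr1 = chrom_len))
}
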