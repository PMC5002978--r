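#' Binned TSS-anchored signal matrix
#'
#' One row per gene, one column per bin tiling the relative extent (e.g.
#' -100..+200 bp in 5-bp bins). Minus-strand genes are orientation-flipped
#' so bin 1 is always the most upstream bin; cell values are sense-strand
#' reads divided by the library size factor. Rows whose window runs off
#' the chromosome are flagged and dropped from composite profiles.
#'
#' @param track a [signal_track()].
#' @param genes gene table.
#' @param extent c(rel_start, rel_end); width must be divisible by
#'   `bin_size`.
#' @param bin_size bin width in bp.
#' @param size_factor library/condition normalization factor.
#' @return list(matrix, bin_centers, flagged) where `matrix` is genes x
#'   bins with gene ids as rownames.
#' @export
bin_profile <- function(track, genes, extent = c(-100, 200), bin_size = 5,
                        size_factor = 1) {
  width <- extent[2] - extent[1]
  stopifnot(width > 0, width %% bin_size == 0)
  n_bins <- width %/% bin_size
  edges <- extent[1] + bin_size * (0:n_bins)
  n <- nrow(genes)
  mat <- matrix(0, n, n_bins, dimnames = list(genes$gene_id, NULL))
  flagged <- logical(n)
  for (i in seq_len(n)) {
    g <- genes[i, ]
    chrom_len <- track$chrom_sizes[[g$chrom]] %||% NULL
    # genomic images of every bin edge, in transcription direction
    if (g$strand == "+") {
      from <- g$tss + edges[-length(edges)]
      to <- g$tss + edges[-1]
    } else {
      from <- g$tss - edges[-1] + 1L
      to <- g$tss - edges[-length(edges)] + 1L
    }
    if (min(from) < 0 || (!is.null(chrom_len) && max(to) > chrom_len)) {
      flagged[i] <- TRUE
      next
    }
    mat[i, ] <- track_window_sums(track, g$chrom, g$strand, from, to) /
      size_factor
  }
  list(matrix = mat, bin_centers = edges[-length(edges)] + bin_size / 2,
       flagged = flagged)
}

#' Composite (metagene) profile with subsampling confidence band
#'
#' Each subsample draws `ceiling(fraction * n)` genes without replacement
#' and records the per-bin mean; the composite is the per-bin median of
#' those subsample means, banded by the central `ci` interval (12.5th and
#' 87.5th percentiles for the default 75% band). Genes are canonically
#' sorted by id before seeding, so the result is independent of input row
#' order.
#'
#' @param matrix genes x bins matrix (rownames = gene ids).
#' @param n_subsamples number of subsamples (default 1000).
#' @param fraction fraction of genes per subsample (default 0.1).
#' @param ci central interval mass (default 0.75).
#' @param seed integer seed for the subsampling stream.
#' @return data.frame: bin, median, lower, upper.
#' @export
composite_profile <- function(matrix, n_subsamples = 1000, fraction = 0.1,
                              ci = 0.75, seed = 1) {
  n <- nrow(matrix)
  if (fraction * n < 1) stop("fraction * n_genes must be at least 1")
  k <- ceiling(fraction * n)
  matrix <- matrix[order(rownames(matrix)), , drop = FALSE]
  set.seed(seed)
  means <- base::matrix(0, n_subsamples, ncol(matrix))
  for (b in seq_len(n_subsamples)) {
    means[b, ] <- colMeans(matrix[sample.int(n, k), , drop = FALSE])
  }
  qs <- apply(means, 2, stats::quantile,
              probs = c((1 - ci) / 2, 0.5, 1 - (1 - ci) / 2),
              type = 7, names = FALSE)
  data.frame(bin = seq_len(ncol(matrix)), median = qs[2, ],
             lower = qs[1, ], upper = qs[3, ])
}

#' Order a binned matrix for heat-map display
#'
#' `distance_to_max_bin` orders genes by the absolute distance between the
#' highest-intensity bin and the TSS (nearest first), as used for pausing
#' heat maps; `fold_change` orders by a supplied per-gene value, highest
#' to lowest. Ties break on gene id so the ordering is deterministic.
#'
#' @param matrix genes x bins matrix (rownames = gene ids).
#' @param ordering "distance_to_max_bin" or "fold_change".
#' @param bin_centers relative bin centers (required for distance
#'   ordering).
#' @param values named per-gene values (required for fold-change
#'   ordering).
#' @return list(matrix = reordered matrix, order_key = data.frame).
#' @export
heatmap_matrix <- function(matrix,
                           ordering = c("distance_to_max_bin",
                                        "fold_change"),
                           bin_centers = NULL, values = NULL) {
  ordering <- match.arg(ordering)
  ids <- rownames(matrix)
  if (ordering == "distance_to_max_bin") {
    stopifnot(!is.null(bin_centers), length(bin_centers) == ncol(matrix))
    key <- abs(bin_centers[apply(matrix, 1, which.max)])
    o <- order(key, ids)
  } else {
    stopifnot(!is.null(values))
    key <- values[ids]
    o <- order(-key, ids)
  }
  list(matrix = matrix[o, , drop = FALSE],
       order_key = data.frame(gene_id = ids[o], key = key[o],
                              row.names = NULL))
}
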