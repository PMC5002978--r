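#' Signed distance from a TSS to the closest ChIP peak
#'
#' Distance is 0 when the TSS lies inside a peak; otherwise it is the gap
#' to the nearest peak edge (half-open intervals, so the last covered base
#' of a peak [s, e) is e-1). The sign follows the transcription direction:
#' positive for a peak downstream of the TSS, negative upstream, so the
#' genomic sign flips for minus-strand genes.
#'
#' @param peaks interval data.frame (chrom, start, end), sorted.
#' @param gene one row of a gene table.
#' @return Signed distance in bp, or NA when the gene's chromosome has no
#'   peak.
#' @export
closest_peak_distance <- function(peaks, gene) {
  pk <- peaks[peaks$chrom == gene$chrom, , drop = FALSE]
  if (nrow(pk) == 0) return(NA_real_)
  tss <- gene$tss
  inside <- tss >= pk$start & tss < pk$end
  if (any(inside)) return(0)
  gap_right <- pk$start - tss      # > 0 when the peak starts right of TSS
  gap_left <- tss - (pk$end - 1)   # > 0 when the peak ends left of TSS
  genomic <- ifelse(gap_right > 0, gap_right, -gap_left)
  d <- genomic[which.min(abs(genomic))]
  if (gene$strand == "-") d <- -d
  d
}

#' Closest-peak distances for every gene
#'
#' @param peaks interval data.frame.
#' @param genes gene table.
#' @return data.frame gene_id, distance (signed, NA when no peak shares
#'   the chromosome).
#' @export
peak_distance_table <- function(peaks, genes) {
  d <- vapply(seq_len(nrow(genes)), function(i) {
    closest_peak_distance(peaks, genes[i, ])
  }, numeric(1))
  data.frame(gene_id = genes$gene_id, distance = d,
             stringsAsFactors = FALSE)
}

#' Genes bound by a factor
#'
#' A gene is bound when a peak lies within +/- `max_dist` bp of its TSS
#' (inclusive boundary).
#'
#' @param peaks interval data.frame.
#' @param genes gene table.
#' @param max_dist maximal |distance| in bp (default 1000).
#' @return Character vector of bound gene ids.
#' @export
bound_genes <- function(peaks, genes, max_dist = 1000) {
  d <- peak_distance_table(peaks, genes)
  d$gene_id[!is.na(d$distance) & abs(d$distance) <= max_dist]
}

#' Compare peak-distance distributions between two gene classes
#'
#' Two-sample Kolmogorov-Smirnov test on absolute TSS-to-peak distances
#' with the asymptotic p-value.
#'
#' @param distances_a,distances_b signed or absolute distances (NAs
#'   dropped).
#' @return list(D, p, n_a, n_b).
#' @export
distance_cdf_compare <- function(distances_a, distances_b) {
  a <- abs(distances_a[!is.na(distances_a)])
  b <- abs(distances_b[!is.na(distances_b)])
  if (length(a) == 0 || length(b) == 0) {
    stop("both samples need at least one finite distance")
  }
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value, n_a = length(a),
       n_b = length(b))
}

#' Factor-enrichment screen between two gene classes
#'
#' For each factor (column of the promoter-signal matrix), a two-sided
#' Mann-Whitney U test compares class A genes against class B genes;
#' rows are ranked by ascending p with the direction given by the sign of
#' the median difference. Factors with constant signal across both
#' classes get p = 1 and are flagged.
#'
#' @param promoter_signal genes x factors numeric matrix (rownames = gene
#'   ids).
#' @param class_a,class_b character vectors of gene ids.
#' @return data.frame: factor, U, p, direction, constant; sorted by p.
#' @export
enrichment_screen <- function(promoter_signal, class_a, class_b) {
  a_ix <- intersect(class_a, rownames(promoter_signal))
  b_ix <- intersect(class_b, rownames(promoter_signal))
  stopifnot(length(a_ix) > 0, length(b_ix) > 0)
  rows <- lapply(colnames(promoter_signal), function(f) {
    xa <- promoter_signal[a_ix, f]
    xb <- promoter_signal[b_ix, f]
    if (length(unique(c(xa, xb))) == 1) {
      return(data.frame(factor = f, U = NA_real_, p = 1,
                        direction = 0, constant = TRUE))
    }
    wt <- suppressWarnings(stats::wilcox.test(xa, xb))
    data.frame(factor = f, U = unname(wt$statistic), p = wt$p.value,
               direction = sign(stats::median(xa) - stats::median(xb)),
               constant = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p, out$factor), , drop = FALSE]
}

#' Promoter-window signal for the enrichment screen
#'
#' Default screen signal: sense-strand reads in `[-750, +750)` around the
#' TSS, the same extent as the display profiles.
#'
#' @param track a [signal_track()] (pooled condition track).
#' @param genes gene table.
#' @param window c(rel_start, rel_end).
#' @return Named numeric vector of per-gene promoter reads.
#' @export
promoter_signal <- function(track, genes, window = c(-750, 750)) {
  w <- relative_window(window[1], window[2])
  v <- vapply(seq_len(nrow(genes)), function(i) {
    count_window(track, genes[i, ], w)$reads
  }, numeric(1))
  stats::setNames(v, genes$gene_id)
}
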