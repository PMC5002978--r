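#' TSS-relative windows
#'
#' Windows are expressed in transcription-direction offsets relative to the
#' TSS (offset 0), half-open `[rel_start, rel_end)`. Paper-style phrases
#' like "-500 to -100 bp of the TSS" are interpreted as the half-open
#' window `[-500, -100)` of length 400.
#'
#' @param rel_start,rel_end integer offsets, `rel_start < rel_end`.
#' @return list with class `relative_window`.
#' @export
relative_window <- function(rel_start, rel_end) {
  stopifnot(rel_start < rel_end)
  structure(list(rel_start = as.integer(rel_start),
                 rel_end = as.integer(rel_end)),
            class = "relative_window")
}

#' Map a TSS-relative window to genomic coordinates
#'
#' Relative offset r maps to genomic position TSS + r on the plus strand
#' and TSS - r on the minus strand, so the genomic image of `[rs, re)` is
#' `[TSS + rs, TSS + re)` (plus) or `[TSS - re + 1, TSS - rs + 1)` (minus).
#' Windows extending beyond the chromosome are clipped and flagged.
#'
#' @param gene one row of a gene table (list or 1-row data.frame).
#' @param w a [relative_window()].
#' @param chrom_length optional chromosome length for right-clipping.
#' @return list(chrom, start, end, clipped); start/end 0-based half-open.
#' @export
to_genomic <- function(gene, w, chrom_length = NULL) {
  tss <- gene$tss
  if (gene$strand == "+") {
    start <- tss + w$rel_start
    end <- tss + w$rel_end
  } else {
    start <- tss - w$rel_end + 1L
    end <- tss - w$rel_start + 1L
  }
  clipped <- FALSE
  if (start < 0) { start <- 0L; clipped <- TRUE }
  if (!is.null(chrom_length) && end > chrom_length) {
    end <- as.integer(chrom_length); clipped <- TRUE
  }
  if (end < start) end <- start
  list(chrom = gene$chrom, start = as.integer(start), end = as.integer(end),
       clipped = clipped)
}

#' Count 3' ends in a TSS-relative window
#'
#' Sums track counts on the gene's own strand (sense) or the opposite
#' strand (antisense) over the genomic image of the window, and reports the
#' mappable-base denominator and read density (reads per mappable base).
#'
#' @param track a [signal_track()].
#' @param gene one row of a gene table.
#' @param w a [relative_window()].
#' @param orientation "sense" or "antisense".
#' @param mappability interval data.frame or NULL (fully mappable).
#' @return list(reads, mappable_bases, density, clipped); density is NA when
#'   no mappable bases fall in the window.
#' @export
count_window <- function(track, gene, w, orientation = c("sense", "antisense"),
                         mappability = NULL) {
  orientation <- match.arg(orientation)
  strand <- gene$strand
  if (orientation == "antisense") strand <- if (strand == "+") "-" else "+"
  chrom_length <- track$chrom_sizes[[gene$chrom]] %||% NULL
  gw <- to_genomic(gene, w, chrom_length)
  reads <- track_window_sums(track, gw$chrom, strand, gw$start, gw$end)
  mb <- mappable_bases(mappability, gw$chrom, gw$start, gw$end)
  list(reads = reads, mappable_bases = mb,
       density = if (mb > 0) reads / mb else NA_real_,
       clipped = gw$clipped)
}

#' Gene-body window for differential analysis
#'
#' The gene body starts 200 bp downstream of the TSS (past the
#' promoter-proximal pause) and ends at the annotated 3' end, except for
#' heat-shock time points where the 3' limit is capped at the distance the
#' elongation wave can have travelled: 1 kb/min times the treatment time.
#'
#' @param gene one row of a gene table.
#' @param t_minutes minutes of heat shock; 0 encodes the NHS control
#'   (no elongation cap).
#' @param body_offset 5' offset of the body, default 200 bp.
#' @param elongation_rate elongation rate in bp/min, default 1000.
#' @return A [relative_window()], or NULL when the capped window is empty
#'   (gene excluded from differential analysis).
#' @export
gene_body_window <- function(gene, t_minutes = 0, body_offset = 200,
                             elongation_rate = 1000) {
  stopifnot(t_minutes >= 0)
  len <- gene$end - gene$start
  limit <- if (t_minutes > 0) min(len, elongation_rate * t_minutes) else len
  if (limit <= body_offset) return(NULL)
  relative_window(body_offset, limit)
}

#' Fraction of reads on the antisense strand over a gene span
#'
#' Computed over the full annotated span. Genes with no reads on either
#' strand return NA (they fail normalization candidacy).
#'
#' @param track a [signal_track()].
#' @param gene one row of a gene table.
#' @return Numeric in [0, 1], or NA when the span has no reads.
#' @export
antisense_fraction <- function(track, gene) {
  sense <- track_window_sums(track, gene$chrom, gene$strand,
                             gene$start, gene$end)
  anti_strand <- if (gene$strand == "+") "-" else "+"
  anti <- track_window_sums(track, gene$chrom, anti_strand,
                            gene$start, gene$end)
  tot <- sense + anti
  if (tot == 0) return(NA_real_)
  anti / tot
}
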