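#' Read a strand pair of bedGraph files into a signal track
#'
#' bedGraph is 4 columns (chrom, start, end, value), 0-based half-open: a
#' line `c s e v` stores count `v` at every position in `[s, e)`. One file
#' per strand, as produced by strand-specific PRO-seq 3'-end pipelines.
#' Track definition lines (`track ...`) and comments (`#`) are skipped.
#'
#' @param plus_path path to the plus-strand bedGraph.
#' @param minus_path path to the minus-strand bedGraph.
#' @param chrom_sizes optional named integer vector of chromosome lengths.
#' @return A [signal_track()].
#' @export
read_bedgraph_pair <- function(plus_path, minus_path, chrom_sizes = NULL) {
  plus <- .read_bedgraph_one(plus_path)
  minus <- .read_bedgraph_one(minus_path)
  chrom <- c(plus$chrom, minus$chrom)
  strand <- c(rep("+", length(plus$pos)), rep("-", length(minus$pos)))
  signal_track(chrom, strand, c(plus$pos, minus$pos),
               c(plus$count, minus$count), chrom_sizes = chrom_sizes)
}

.read_bedgraph_one <- function(path) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|#)", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    return(list(chrom = character(), pos = integer(), count = numeric()))
  }
  dt <- data.table::fread(text = lines[keep], header = FALSE, sep = "\t")
  if (ncol(dt) == 1) {  # space-separated fallback
    dt <- data.table::fread(text = lines[keep], header = FALSE, sep = " ")
  }
  if (ncol(dt) != 4) {
    stop("malformed bedGraph (expected 4 columns): ", path)
  }
  data.table::setnames(dt, c("chrom", "start", "end", "value"))
  line_no <- which(keep)
  bad <- which(!is.finite(dt$start) | !is.finite(dt$end) | dt$start < 0 |
                 dt$start >= dt$end)
  if (length(bad) > 0) {
    stop(sprintf("malformed interval in %s at line %d", path, line_no[bad[1]]))
  }
  neg <- which(dt$value < 0)
  if (length(neg) > 0) {
    stop(sprintf("negative value in %s at line %d", path, line_no[neg[1]]))
  }
  widths <- dt$end - dt$start
  list(chrom = rep(dt$chrom, widths),
       pos = rep(dt$start, widths) + (sequence(widths) - 1L),
       count = rep(dt$value, widths))
}

#' Write a signal track as a bedGraph strand pair
#'
#' Adjacent equal-count positions are merged into maximal intervals and
#' zero-count positions omitted; output is sorted by (chrom, start) so the
#' writer is deterministic. `write_bedgraph` then `read_bedgraph_pair` is
#' the identity on any track.
#'
#' @param track a [signal_track()].
#' @param out_plus,out_minus output paths for the two strands.
#' @return Invisibly, the two paths.
#' @export
write_bedgraph <- function(track, out_plus, out_minus) {
  for (s in c("+", "-")) {
    out <- if (s == "+") out_plus else out_minus
    dt <- track$data[strand == s][order(chrom, pos)]
    if (nrow(dt) == 0) {
      cat("", file = out)
      next
    }
    run <- cumsum(c(TRUE, dt$chrom[-1] != dt$chrom[-nrow(dt)] |
                      dt$pos[-1] != dt$pos[-nrow(dt)] + 1L |
                      dt$count[-1] != dt$count[-nrow(dt)]))
    merged <- dt[, list(chrom = chrom[1], start = pos[1],
                        end = pos[length(pos)] + 1L, value = count[1]),
                 by = list(run = run)][, -"run"]
    utils::write.table(format(merged, scientific = FALSE, trim = TRUE),
                       out, quote = FALSE, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(c(out_plus, out_minus))
}

#' Read gene annotations from BED6
#'
#' One transcription unit per gene. The TSS is the first transcribed base:
#' `start` for plus-strand genes, `end - 1` for minus-strand genes (0-based
#' half-open spans). Output is sorted by (chrom, start).
#'
#' @param bed_path path to a BED6 file.
#' @return data.frame with columns gene_id, chrom, start, end, strand, tss.
#' @export
read_genes <- function(bed_path) {
  dt <- .read_bed(bed_path, min_cols = 6)
  gene_table(gene_id = dt$V4, chrom = dt$V1, start = dt$V2, end = dt$V3,
             strand = dt$V6)
}

#' Construct a gene table
#'
#' @param gene_id character gene identifiers (unique).
#' @param chrom,start,end,strand genomic spans, 0-based half-open.
#' @return data.frame sorted by (chrom, start) with a `tss` column.
#' @export
gene_table <- function(gene_id, chrom, start, end, strand) {
  stopifnot(all(start < end), all(strand %in% c("+", "-")),
            !anyDuplicated(gene_id))
  g <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                  start = as.integer(start), end = as.integer(end),
                  strand = as.character(strand), stringsAsFactors = FALSE)
  g$tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  g[order(g$chrom, g$start, g$gene_id), , drop = FALSE]
}

#' Read intervals (peaks, mappability) from BED3+
#'
#' @param bed_path path to a BED file with at least 3 columns; column 5
#'   (score) is kept when present.
#' @return data.frame with chrom, start, end (0-based half-open) and score,
#'   sorted by (chrom, start).
#' @export
read_intervals <- function(bed_path) {
  dt <- .read_bed(bed_path, min_cols = 3)
  out <- data.frame(chrom = dt$V1, start = as.integer(dt$V2),
                    end = as.integer(dt$V3),
                    score = if (ncol(dt) >= 5) as.numeric(dt$V5) else NA_real_,
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}

.read_bed <- function(path, min_cols) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|#)", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    dt <- data.table::as.data.table(
      stats::setNames(rep(list(character(0)), min_cols),
                      paste0("V", seq_len(min_cols))))
    dt$V2 <- integer(0); dt$V3 <- integer(0)
    return(dt)
  }
  dt <- data.table::fread(text = lines[keep], header = FALSE)
  if (ncol(dt) < min_cols) {
    stop(sprintf("BED file %s has %d columns; %d required", path, ncol(dt),
                 min_cols))
  }
  if (any(dt$V2 >= dt$V3)) {
    stop("BED file ", path, ": start must be < end")
  }
  dt
}

#' Write a gene table or interval table as BED
#'
#' @param x a gene table (writes BED6) or interval data.frame (BED3/BED5).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path) {
  if ("gene_id" %in% names(x)) {
    out <- data.frame(x$chrom, x$start, x$end, x$gene_id, 0L, x$strand)
  } else if (all(is.na(x$score %||% NA))) {
    out <- data.frame(x$chrom, x$start, x$end)
  } else {
    out <- data.frame(x$chrom, x$start, x$end, ".", x$score)
  }
  out <- out[order(out[[1]], out[[2]]), , drop = FALSE]
  utils::write.table(out, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Count mappable bases overlapping a genomic window
#'
#' `mappability` is a data.frame of sorted, non-overlapping 0-based
#' half-open intervals per chromosome, or NULL meaning every position is
#' mappable (the default for synthetic data).
#'
#' @param mappability interval data.frame (chrom, start, end) or NULL.
#' @param chrom chromosome name.
#' @param from,to window bounds, 0-based half-open.
#' @return Integer number of mappable bases in `[from, to)`.
#' @export
mappable_bases <- function(mappability, chrom, from, to) {
  if (to <= from) return(0L)
  if (is.null(mappability)) return(as.integer(to - from))
  iv <- mappability[mappability$chrom == chrom, , drop = FALSE]
  if (nrow(iv) == 0) return(0L)
  as.integer(sum(pmax(0, pmin(iv$end, to) - pmax(iv$start, from))))
}
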