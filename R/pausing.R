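#' Locate the promoter-proximal pause window of a gene
#'
#' The pause region is the 50-bp window with the most 3'-end reads among
#' all candidate windows `[s, s+50)` with start s in -50..+100 (TSS =
#' offset 0). It is detected once in the reference condition (the pooled
#' control NHS track) and the same window is reused for every other
#' treatment, so between-condition pausing comparisons are over identical
#' coordinates. Ties break to the most upstream start, so zero-signal
#' genes get `[-50, 0)`.
#'
#' @param track reference-condition [signal_track()].
#' @param gene one row of a gene table.
#' @param config an [analysis_config()].
#' @return A [relative_window()] of width `config$pause_width`.
#' @export
find_pause_window <- function(track, gene, config = analysis_config()) {
  lo <- config$pause_search[1]
  hi <- config$pause_search[2]
  width <- config$pause_width
  starts <- lo:(hi - width)
  # per-offset counts across the search space, then a rolling window sum
  span <- to_genomic(gene, relative_window(lo, hi),
                     track$chrom_sizes[[gene$chrom]] %||% NULL)
  hits <- track_positions(track, span$chrom, gene$strand, span$start,
                          span$end)
  off <- if (gene$strand == "+") hits$pos - gene$tss else gene$tss - hits$pos
  per_off <- numeric(hi - lo)
  if (nrow(hits) > 0) {
    ix <- off - lo + 1L
    per_off[ix] <- per_off[ix] + hits$count
  }
  cum <- c(0, cumsum(per_off))
  wsum <- cum[(starts - lo) + width + 1L] - cum[(starts - lo) + 1L]
  s <- starts[which.max(wsum)]  # which.max takes the first (most upstream)
  relative_window(s, s + width)
}

#' Pausing index
#'
#' Ratio of the read density (reads per mappable base) in the pause region
#' to the read density in the gene body.
#'
#' @param pause,body region counts as returned by [count_window()].
#' @return PI, or NA when the body density is zero or undefined.
#' @export
pausing_index <- function(pause, body) {
  if (is.na(body$density) || body$density == 0 || is.na(pause$density)) {
    return(NA_real_)
  }
  pause$density / body$density
}

#' Fisher's exact test for paused-gene classification
#'
#' One-sided test for enrichment of reads in the pause region relative to
#' its share of mappable bases, on the 2x2 table
#' rows = (reads, mappable bases), columns = (pause region, gene body).
#' A gene is called paused when p <= 0.01.
#'
#' @param pause_reads,body_reads integer read counts.
#' @param pause_mappable,body_mappable mappable-base denominators (> 0).
#' @return One-sided p-value (1 for a degenerate all-zero table).
#' @export
paused_test <- function(pause_reads, body_reads, pause_mappable,
                        body_mappable) {
  stopifnot(pause_mappable > 0, body_mappable > 0,
            pause_reads >= 0, body_reads >= 0)
  if (pause_reads + body_reads == 0) return(1)
  tab <- matrix(round(c(pause_reads, pause_mappable,
                        body_reads, body_mappable)), 2, 2)
  stats::fisher.test(tab, alternative = "greater")$p.value
}

#' Per-gene pausing summary across conditions
#'
#' Fixes the pause window per gene from the reference (pooled control NHS)
#' track, then computes pause counts, pausing indices and the paused call
#' in each condition's pooled track.
#'
#' @param reference_track pooled control NHS [signal_track()] used to fix
#'   the windows.
#' @param condition_tracks named list of pooled per-condition tracks.
#' @param genes gene table.
#' @param config an [analysis_config()].
#' @param mappability interval data.frame or NULL.
#' @return data.frame with one row per gene: window offsets, and per
#'   condition pause reads, PI, fisher p and paused flag.
#' @export
pausing_table <- function(reference_track, condition_tracks, genes,
                          config = analysis_config(), mappability = NULL) {
  n <- nrow(genes)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    g <- genes[i, ]
    w <- find_pause_window(reference_track, g, config)
    bodyw <- gene_body_window(g, 0, config$body_offset)
    row <- list(gene_id = g$gene_id, pause_start = w$rel_start,
                pause_end = w$rel_end)
    for (cond in names(condition_tracks)) {
      tr <- condition_tracks[[cond]]
      pc <- count_window(tr, g, w, mappability = mappability)
      if (is.null(bodyw)) {
        pi_v <- NA_real_; p_v <- NA_real_; reads_b <- NA_real_
      } else {
        bc <- count_window(tr, g, bodyw, mappability = mappability)
        pi_v <- pausing_index(pc, bc)
        p_v <- paused_test(pc$reads, bc$reads, pc$mappable_bases,
                           bc$mappable_bases)
        reads_b <- bc$reads
      }
      row[[paste0("pause_reads_", cond)]] <- pc$reads
      row[[paste0("body_reads_", cond)]] <- reads_b
      row[[paste0("pi_", cond)]] <- pi_v
      row[[paste0("fisher_p_", cond)]] <- p_v
      row[[paste0("paused_", cond)]] <- !is.na(p_v) &&
        p_v <= config$paused_alpha
    }
    rows[[i]] <- row
  }
  out <- data.table::rbindlist(rows)
  data.table::setDF(out)
  out
}

#' Differential test on pause-region counts
#'
#' Collects per-library pause-region counts inside windows fixed from the
#' reference condition and delegates to the NB Wald machinery of the
#' differential module (FDR 0.001 by default), identifying genes whose
#' pausing level changes after heat shock.
#'
#' @param reference_track pooled control NHS track fixing the windows.
#' @param tracks named list of per-library tracks.
#' @param genes gene table.
#' @param size_factors numeric per library.
#' @param conditions condition labels per library.
#' @param config an [analysis_config()].
#' @param reference baseline condition label.
#' @return data.frame as from [differential_test()].
#' @export
pausing_change_test <- function(reference_track, tracks, genes, size_factors,
                                conditions, config = analysis_config(),
                                reference = "NHS") {
  counts <- matrix(0, nrow(genes), length(tracks),
                   dimnames = list(genes$gene_id, names(tracks)))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    w <- find_pause_window(reference_track, g, config)
    for (j in seq_along(tracks)) {
      counts[i, j] <- count_window(tracks[[j]], g, w)$reads
    }
  }
  differential_test(counts, size_factors, conditions, config,
                    reference = reference)
}
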