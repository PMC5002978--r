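#' Z-score a per-gene signal vector
#'
#' z_i = (x_i - mean) / sd with the sample (n-1) standard deviation.
#'
#' @param values numeric vector (length >= 2, non-constant).
#' @return Numeric vector of z-scores.
#' @export
zscore_signal <- function(values) {
  if (length(values) < 2) stop("need at least two values to z-score")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("zero variance: z-scores undefined")
  (values - mean(values)) / s
}

#' Select the invariant ("unchanged") gene set for normalization
#'
#' Applies three filters in order, each anchored on a different data type:
#' (1) antisense filter - the fraction of reads on the antisense strand
#' over the gene span must be <= `antisense_max` in both the NHS and HS
#' control condition (pooled across libraries), so the gene's signal is
#' cleanly sense-stranded; (2) ChIP filter - the Ser2-P style ChIP signal
#' z-score must exceed `zscore_min`, restricting to genes with the highest
#' elongating-polymerase signal over ChIP background; (3) stability filter
#' - the HS/NHS gene-body fold change, computed on depth-scaled reads
#' summed across the libraries of each condition, must lie inside
#' `fc_window`. The full-gene NHS body window is used in both conditions
#' (selection precedes the differential stage and its time-capped
#' windows).
#'
#' Genome-wide transcription changes make raw or total-read scaled fold
#' changes systematically off-center (the very problem invariant-set
#' normalization addresses), so the stability filter anchors each fold
#' change at the median fold change of the genes that already passed the
#' antisense and ChIP filters - a candidate pool dominated by invariant
#' genes by construction - before applying the window. `fc_scale = "raw"`
#' disables both the depth scaling and the centering.
#'
#' @param tracks_nhs,tracks_hs lists of [signal_track()] per library.
#' @param genes gene table.
#' @param chip_signal numeric per-gene ChIP signal, aligned with `genes`.
#' @param config an [analysis_config()].
#' @param mappability interval data.frame or NULL.
#' @param fc_scale "depth" (default) scales each library by its total read
#'   count before condition sums; "raw" uses raw sums.
#' @return list(unchanged = character gene ids, audit = data.frame with
#'   per-gene filter values and a `passed` flag plus failure reason).
#' @export
select_unchanged_genes <- function(tracks_nhs, tracks_hs, genes, chip_signal,
                                   config = analysis_config(),
                                   mappability = NULL,
                                   fc_scale = c("depth", "raw")) {
  fc_scale <- match.arg(fc_scale)
  stopifnot(length(chip_signal) == nrow(genes))
  pool_nhs <- pool_tracks(tracks_nhs)
  pool_hs <- pool_tracks(tracks_hs)

  n <- nrow(genes)
  as_nhs <- as_hs <- numeric(n)
  body_nhs <- body_hs <- matrix(0, n, max(length(tracks_nhs),
                                          length(tracks_hs)))
  for (i in seq_len(n)) {
    g <- genes[i, ]
    as_nhs[i] <- antisense_fraction(pool_nhs, g)
    as_hs[i] <- antisense_fraction(pool_hs, g)
    w <- gene_body_window(g, 0, config$body_offset)
    if (!is.null(w)) {
      for (j in seq_along(tracks_nhs)) {
        body_nhs[i, j] <- count_window(tracks_nhs[[j]], g, w)$reads
      }
      for (j in seq_along(tracks_hs)) {
        body_hs[i, j] <- count_window(tracks_hs[[j]], g, w)$reads
      }
    }
  }
  if (fc_scale == "depth") {
    d_nhs <- vapply(tracks_nhs, track_total, numeric(1))
    d_hs <- vapply(tracks_hs, track_total, numeric(1))
    dall <- geomean(c(d_nhs, d_hs))
    s_nhs <- body_nhs %*% (dall / d_nhs)
    s_hs <- body_hs %*% (dall / d_hs)
  } else {
    s_nhs <- rowSums(body_nhs)
    s_hs <- rowSums(body_hs)
  }
  body_fc <- ifelse(s_nhs > 0, s_hs / s_nhs, NA_real_)

  chip_z <- if (config$zscore_transform == "log10") {
    x <- chip_signal
    if (any(x <= 0)) x <- pmax(x, min(x[x > 0]) / 10)
    zscore_signal(log10(x))
  } else {
    zscore_signal(chip_signal)
  }

  pass_as <- !is.na(as_nhs) & !is.na(as_hs) &
    as_nhs <= config$antisense_max & as_hs <= config$antisense_max
  pass_z <- chip_z > config$zscore_min
  if (fc_scale == "depth") {
    anchor <- stats::median(body_fc[pass_as & pass_z], na.rm = TRUE)
    if (is.finite(anchor) && anchor > 0) body_fc <- body_fc / anchor
  }
  pass_fc <- !is.na(body_fc) & body_fc >= config$fc_window[1] &
    body_fc <= config$fc_window[2]
  passed <- pass_as & pass_z & pass_fc
  reason <- rep(NA_character_, n)
  reason[!pass_fc] <- "fold_change"
  reason[!pass_z] <- "chip_zscore"
  reason[!pass_as] <- "antisense"
  reason[passed] <- NA_character_

  audit <- data.frame(gene_id = genes$gene_id, antisense_nhs = as_nhs,
                      antisense_hs = as_hs, chip_zscore = chip_z,
                      body_fc = body_fc, passed = passed,
                      failure_reason = reason, stringsAsFactors = FALSE)
  if (!any(passed)) {
    stop("no genes pass the invariant-set filters; relax antisense_max, ",
         "zscore_min or fc_window")
  }
  list(unchanged = genes$gene_id[passed], audit = audit)
}

#' Compute between-library size factors from the invariant gene set
#'
#' For library l, S_l is the sum of raw gene-body reads over the unchanged
#' genes; the size factor is S_l divided by the geometric mean of all S,
#' so factors multiply to 1 and normalized counts are raw / factor.
#'
#' @param tracks named list of [signal_track()] per library.
#' @param genes gene table.
#' @param unchanged character vector of invariant gene ids.
#' @param config an [analysis_config()].
#' @return list(size_factors = named numeric, reference_sums = named
#'   numeric of per-library unchanged-gene body totals).
#' @export
compute_size_factors <- function(tracks, genes, unchanged,
                                 config = analysis_config()) {
  if (length(unchanged) == 0) stop("unchanged gene set is empty")
  sel <- genes[genes$gene_id %in% unchanged, , drop = FALSE]
  sums <- vapply(seq_along(tracks), function(j) {
    tot <- 0
    for (i in seq_len(nrow(sel))) {
      g <- sel[i, ]
      w <- gene_body_window(g, 0, config$body_offset)
      if (!is.null(w)) tot <- tot + count_window(tracks[[j]], g, w)$reads
    }
    tot
  }, numeric(1))
  names(sums) <- names(tracks) %||% paste0("lib", seq_along(tracks))
  if (any(sums == 0)) {
    stop("library ", names(sums)[which(sums == 0)[1]],
         " has no reads in the unchanged gene set")
  }
  list(size_factors = sums / geomean(sums), reference_sums = sums)
}
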