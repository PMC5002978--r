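#' Analysis configuration
#'
#' Every numeric threshold of the pipeline in one place. Defaults are the
#' standard values of the heat-shock PRO-seq workflow: antisense fraction
#' <= 0.2 and ChIP z-score > 3 with a 0.85-1.15 stability window for the
#' invariant normalization set; FDR 0.001 for differential calls with
#' unchanged defined as padj > 0.5 and |log2 fc| < 0.25; gene bodies from
#' +200 bp with a 1 kb/min elongation-limited 3' cap; upstream-ratio
#' windows [-500, -100) and [+300, +700) with cutoff 0.23; pause search
#' [-50, +150) with a 50-bp window and paused calls at Fisher p <= 0.01;
#' bound genes within 1 kb of a peak; composites from 1000 subsamples of
#' 10% with a 75% band.
#'
#' @param antisense_max maximal antisense fraction for invariant-set
#'   candidates.
#' @param zscore_min minimal ChIP signal z-score.
#' @param zscore_transform "log10" or "raw" signal transform before
#'   z-scoring.
#' @param fc_window stability window (low, high) for candidate fold
#'   changes.
#' @param de_fdr FDR for activated/repressed calls.
#' @param unchanged_padj,unchanged_abs_lfc unchanged-class thresholds.
#' @param upstream_cutoff upstream-ratio cutoff.
#' @param upstream_window,upstream_body_window relative windows for the
#'   upstream ratio.
#' @param body_offset gene-body 5' offset (bp downstream of the TSS).
#' @param elongation_rate assumed Pol II elongation rate, bp/min.
#' @param pause_search pause-window search space (relative, half-open).
#' @param pause_width pause-window width, bp.
#' @param paused_alpha Fisher p threshold for the paused call.
#' @param bound_dist maximal TSS-to-peak distance for a bound call, bp.
#' @param n_subsamples,subsample_fraction,ci composite-profile settings.
#' @param seed integer seed for subsampling.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(antisense_max = 0.2,
                            zscore_min = 3.0,
                            zscore_transform = "log10",
                            fc_window = c(0.85, 1.15),
                            de_fdr = 0.001,
                            unchanged_padj = 0.5,
                            unchanged_abs_lfc = 0.25,
                            upstream_cutoff = 0.23,
                            upstream_window = c(-500, -100),
                            upstream_body_window = c(300, 700),
                            body_offset = 200,
                            elongation_rate = 1000,
                            pause_search = c(-50, 150),
                            pause_width = 50,
                            paused_alpha = 0.01,
                            bound_dist = 1000,
                            n_subsamples = 1000,
                            subsample_fraction = 0.1,
                            ci = 0.75,
                            seed = 1) {
  cfg <- as.list(environment())
  stopifnot(antisense_max >= 0, antisense_max <= 1, zscore_min > 0,
            zscore_transform %in% c("log10", "raw"),
            fc_window[1] < 1, fc_window[2] > 1,
            de_fdr > 0, de_fdr < 1, unchanged_padj > 0,
            unchanged_abs_lfc > 0, upstream_cutoff >= 0,
            upstream_window[1] < upstream_window[2],
            upstream_body_window[1] < upstream_body_window[2],
            body_offset >= 0, elongation_rate > 0,
            pause_search[1] < pause_search[2],
            pause_width > 0,
            pause_width <= pause_search[2] - pause_search[1],
            paused_alpha > 0, bound_dist >= 0, n_subsamples >= 1,
            subsample_fraction > 0, subsample_fraction <= 1,
            ci > 0, ci < 1)
  class(cfg) <- "analysis_config"
  cfg
}

#' Run the full heat-shock PRO-seq pipeline
#'
#' Stages: invariant-set selection and size factors from the control
#' condition pair; gene-body counting with the contrast's
#' elongation-capped window; NB differential test and classification;
#' upstream-ratio filter (activated genes on the HS ratio, repressed on
#' the NHS ratio); pausing table and pausing-change test; composite
#' profiles per class; optional TF peak statistics. All stages are pure
#' functions of (inputs, config, seed); the run report records the
#' thresholds and the gene counts at each step.
#'
#' @param tracks named list of per-library [signal_track()].
#' @param design design data.frame (library_index, condition, t_minutes).
#' @param genes gene table.
#' @param chip_signal per-gene ChIP signal aligned with `genes`.
#' @param config an [analysis_config()].
#' @param mappability interval data.frame or NULL.
#' @param peaks optional named list of peak interval data.frames.
#' @param profile_extent,profile_bin composite-profile extent and bin
#'   size.
#' @return list(report, unchanged, size_factors, differential, filtered,
#'   pausing, pausing_change, profiles, tf).
#' @export
run_pipeline <- function(tracks, design, genes, chip_signal,
                         config = analysis_config(), mappability = NULL,
                         peaks = NULL, profile_extent = c(-100, 200),
                         profile_bin = 5) {
  stopifnot(length(tracks) == nrow(design))
  is_nhs <- design$condition == "NHS"
  if (!any(is_nhs) || !any(!is_nhs)) stop("need NHS and HS libraries")
  t_hs <- unique(design$t_minutes[!is_nhs])
  if (length(t_hs) != 1) stop("one HS time point per run")

  # 1. invariant gene set + size factors
  sel <- select_unchanged_genes(tracks[is_nhs], tracks[!is_nhs], genes,
                                chip_signal, config, mappability)
  sf <- compute_size_factors(tracks, genes, sel$unchanged, config)

  # 2. gene-body counts + differential test
  bc <- body_count_matrix(tracks, genes, t_hs, config)
  de <- differential_test(bc$counts, sf$size_factors, design$condition,
                          config, reference = "NHS")

  # 3. upstream-ratio filter
  pool_nhs <- pool_tracks(tracks[is_nhs])
  pool_hs <- pool_tracks(tracks[!is_nhs])
  r_nhs <- upstream_ratio_table(pool_nhs, genes, config, mappability)
  r_hs <- upstream_ratio_table(pool_hs, genes, config, mappability)
  filt <- apply_runthrough_filter(de[, c("gene_id", "class")], r_nhs, r_hs,
                                  config$upstream_cutoff)

  # 4. pausing
  cond_tracks <- list(NHS = pool_nhs, HS = pool_hs)
  pause <- pausing_table(pool_nhs, cond_tracks, genes, config, mappability)
  pause_de <- pausing_change_test(pool_nhs, tracks, genes, sf$size_factors,
                                  design$condition, config)

  # 5. composite profiles per filtered class (pooled HS signal)
  final_class <- stats::setNames(filt$classes$filtered_class,
                                 filt$classes$gene_id)
  bp <- bin_profile(pool_hs, genes, profile_extent, profile_bin)
  profiles <- list()
  for (cl in c("activated", "repressed", "unchanged")) {
    ids <- names(final_class)[final_class == cl & !is.na(final_class)]
    ids <- setdiff(ids, rownames(bp$matrix)[bp$flagged])
    if (length(ids) >= 10) {
      profiles[[cl]] <- composite_profile(
        bp$matrix[ids, , drop = FALSE], config$n_subsamples,
        config$subsample_fraction, config$ci, seed = config$seed)
    }
  }

  # 6. TF binding statistics
  tf <- NULL
  if (!is.null(peaks)) {
    tf <- lapply(peaks, function(pk) {
      dist <- peak_distance_table(pk, genes)
      list(distances = dist,
           bound = bound_genes(pk, genes, config$bound_dist))
    })
  }

  cls_tab <- function(x) as.list(table(factor(
    x, levels = c("activated", "repressed", "unchanged", "ambiguous",
                  "removed_runthrough"))))
  report <- list(
    seed = config$seed,
    thresholds = config[c("antisense_max", "zscore_min", "fc_window",
                          "de_fdr", "unchanged_padj", "unchanged_abs_lfc",
                          "upstream_cutoff", "body_offset",
                          "elongation_rate", "paused_alpha", "bound_dist")],
    hs_time_minutes = t_hs,
    n_genes = nrow(genes),
    n_excluded_empty_body = nrow(bc$excluded),
    n_unchanged_set = length(sel$unchanged),
    size_factors = as.list(sf$size_factors),
    classes_pre_filter = cls_tab(de$class),
    classes_post_filter = cls_tab(filt$classes$filtered_class),
    filter_rule = list(activated = "HS upstream ratio",
                       repressed = "NHS upstream ratio",
                       cutoff = config$upstream_cutoff),
    n_paused_nhs = sum(pause$paused_NHS, na.rm = TRUE),
    n_pausing_change = sum(pause_de$padj <= config$de_fdr, na.rm = TRUE))

  list(report = report, unchanged = sel, size_factors = sf,
       differential = de, filtered = filt, pausing = pause,
       pausing_change = pause_de, profiles = profiles, tf = tf)
}

#' Write a run report as JSON
#'
#' @param report report list from [run_pipeline()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
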