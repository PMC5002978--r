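#' Upstream ratio of a gene
#'
#' Ratio of the mappability-adjusted sense-strand read density in the
#' window upstream of the TSS (`[-500, -100)`, stopping 100 bp short of
#' the TSS to dodge misannotated starts) to the density in a gene-body
#' window (`[+300, +700)`, starting past the promoter-proximal pause
#' peak). High values flag genes whose apparent signal is run-through
#' transcription from an upstream neighbor.
#'
#' @param track a [signal_track()] (one condition, libraries pooled).
#' @param gene one row of a gene table.
#' @param config an [analysis_config()].
#' @param mappability interval data.frame or NULL.
#' @return list(upstream_density, body_density, ratio); ratio is NA when
#'   the body density is zero or undefined (gene excluded from filtering).
#' @export
upstream_ratio <- function(track, gene, config = analysis_config(),
                           mappability = NULL) {
  up <- count_window(track, gene,
                     relative_window(config$upstream_window[1],
                                     config$upstream_window[2]),
                     mappability = mappability)
  body <- count_window(track, gene,
                       relative_window(config$upstream_body_window[1],
                                       config$upstream_body_window[2]),
                       mappability = mappability)
  ratio <- if (is.na(body$density) || body$density == 0 ||
                 is.na(up$density)) {
    NA_real_
  } else {
    up$density / body$density
  }
  list(upstream_density = up$density, body_density = body$density,
       ratio = ratio)
}

#' Grid search for the accuracy-optimal upstream-ratio cutoff
#'
#' A gene is retained when its ratio is <= the cutoff. For each candidate
#' cutoff on the grid 0, 0.01, ..., 1, accuracy is
#' (true positives retained + false positives removed) / total; the chosen
#' cutoff is the smallest grid value attaining maximal accuracy (the most
#' stringent filter among ties).
#'
#' @param ratios numeric upstream ratios of labeled genes.
#' @param is_true logical: TRUE for genuine positives, FALSE for
#'   run-through false positives.
#' @param grid candidate cutoffs.
#' @return list(grid, accuracy, cutoff, best_accuracy).
#' @export
optimize_cutoff <- function(ratios, is_true,
                            grid = seq(0, 1, by = 0.01)) {
  stopifnot(length(ratios) == length(is_true), length(ratios) > 0,
            !any(is.na(ratios)))
  acc <- vapply(grid, function(c) {
    (sum(is_true & ratios <= c) + sum(!is_true & ratios > c)) /
      length(ratios)
  }, numeric(1))
  best <- max(acc)
  list(grid = grid, accuracy = acc,
       cutoff = grid[which(acc == best)[1]], best_accuracy = best)
}

#' Filter differential classes on the upstream ratio
#'
#' Genes with an upstream ratio strictly above the cutoff are removed from
#' the activated and repressed classes. The condition with the higher
#' PRO-seq level is used for each class: activated genes are filtered on
#' their HS ratio and repressed genes on their NHS ratio. Genes with an
#' undefined ratio are retained and flagged.
#'
#' @param classes data.frame with gene_id and class columns.
#' @param ratio_nhs,ratio_hs named numeric upstream ratios per gene
#'   (names = gene ids) for the two conditions.
#' @param cutoff upstream-ratio cutoff (default the shipped 0.23).
#' @return list(classes = data.frame with filtered class and `removed`
#'   flag, audit = data.frame of removal decisions).
#' @export
apply_runthrough_filter <- function(classes, ratio_nhs, ratio_hs,
                                    cutoff = 0.23) {
  cls <- classes$class
  used_ratio <- rep(NA_real_, nrow(classes))
  act <- which(cls == "activated")
  rep_ <- which(cls == "repressed")
  used_ratio[act] <- ratio_hs[classes$gene_id[act]]
  used_ratio[rep_] <- ratio_nhs[classes$gene_id[rep_]]
  removed <- !is.na(used_ratio) & used_ratio > cutoff
  flagged <- (cls %in% c("activated", "repressed")) & is.na(used_ratio)
  out <- classes
  out$filtered_class <- cls
  out$filtered_class[removed] <- "removed_runthrough"
  out$removed <- removed
  out$ratio_missing <- flagged
  audit <- data.frame(gene_id = classes$gene_id, class = cls,
                      filter_condition = ifelse(
                        cls == "activated", "HS",
                        ifelse(cls == "repressed", "NHS", NA)),
                      ratio = used_ratio, removed = removed,
                      stringsAsFactors = FALSE)
  list(classes = out, audit = audit[cls %in% c("activated", "repressed"), ,
                                    drop = FALSE])
}

#' Upstream ratios for every gene in one condition
#'
#' @param track pooled [signal_track()] for the condition.
#' @param genes gene table.
#' @param config an [analysis_config()].
#' @param mappability interval data.frame or NULL.
#' @return Named numeric vector of ratios (NA where undefined).
#' @export
upstream_ratio_table <- function(track, genes, config = analysis_config(),
                                 mappability = NULL) {
  r <- vapply(seq_len(nrow(genes)), function(i) {
    upstream_ratio(track, genes[i, ], config, mappability)$ratio
  }, numeric(1))
  stats::setNames(r, genes$gene_id)
}
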