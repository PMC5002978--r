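#' Method-of-moments negative-binomial dispersion for one gene
#'
#' Counts are first normalized by the size factors, each condition is
#' centered at its own mean (so real between-condition differences do not
#' inflate the estimate), and the pooled variance uses n - k degrees of
#' freedom for k conditions. The dispersion is
#' alpha = max(alpha_floor, (var - mean) / mean^2), the moment inversion of
#' the NB variance m + alpha m^2.
#'
#' @param counts_row integer counts across libraries for one gene.
#' @param size_factors numeric size factors per library.
#' @param conditions character/factor condition labels per library.
#' @param alpha_floor lower bound, default 1e-8.
#' @return Dispersion alpha, or NA for an all-zero row.
#' @export
estimate_dispersion <- function(counts_row, size_factors, conditions,
                                alpha_floor = 1e-8) {
  stopifnot(length(counts_row) == length(size_factors),
            length(counts_row) == length(conditions))
  if (all(counts_row == 0)) return(NA_real_)
  norm <- counts_row / size_factors
  res <- unlist(lapply(split(norm, conditions), function(x) x - mean(x)),
                use.names = FALSE)
  df <- length(norm) - length(unique(conditions))
  if (df <= 0) stop("need more libraries than conditions")
  v <- sum(res^2) / df
  m <- mean(norm)
  max(alpha_floor, (v - m) / m^2)
}

#' Negative-binomial Wald test for one gene
#'
#' The log2 fold change is the ratio of condition means of normalized
#' counts (reference condition in the denominator), with a 0.5 pseudocount
#' when either mean is zero. Its standard error comes from the NB variance
#' of each condition mean by the delta method, and the two-sided p-value
#' from the normal reference for the Wald statistic lfc / SE.
#'
#' @param counts_row integer counts across libraries.
#' @param size_factors numeric size factors per library.
#' @param conditions condition labels per library.
#' @param alpha NB dispersion used for the variance.
#' @param reference the baseline condition (default "NHS").
#' @return list(log2fc, se, p, mean_norm).
#' @export
nb_wald_test <- function(counts_row, size_factors, conditions, alpha,
                         reference = "NHS") {
  conditions <- as.character(conditions)
  stopifnot(reference %in% conditions, length(unique(conditions)) == 2)
  is_ref <- conditions == reference
  norm <- counts_row / size_factors
  mA <- mean(norm[is_ref])   # reference (NHS)
  mB <- mean(norm[!is_ref])  # treatment (HS)
  pseudo <- if (mA == 0 || mB == 0) 0.5 else 0
  lfc <- log2((mB + pseudo) / (mA + pseudo))
  # Var(mean of K_l / s_l) with Var(K_l) = m s_l + alpha m^2 s_l^2
  vA <- sum(mA / size_factors[is_ref] + alpha * mA^2) / sum(is_ref)^2
  vB <- sum(mB / size_factors[!is_ref] + alpha * mB^2) / sum(!is_ref)^2
  v_log <- vA / (mA + pseudo)^2 + vB / (mB + pseudo)^2
  se <- sqrt(v_log) / log(2)
  z <- if (se > 0) lfc / se else 0
  list(log2fc = lfc, se = se, p = 2 * stats::pnorm(-abs(z)),
       mean_norm = mean(norm))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Explicit step-up with monotonicity enforcement; NA p-values propagate
#' as NA without entering the ranking.
#'
#' @param pvalues numeric vector in [0, 1] (NAs allowed).
#' @return Adjusted p-values (FDR).
#' @export
bh_adjust <- function(pvalues) {
  out <- rep(NA_real_, length(pvalues))
  ok <- which(!is.na(pvalues))
  m <- length(ok)
  if (m == 0) return(out)
  p <- pvalues[ok]
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(m / seq(m, 1) * p[o]))
  out[ok[o]] <- adj
  out
}

#' Classify genes from adjusted p-values and fold changes
#'
#' activated: padj <= fdr and log2fc > 0; repressed: padj <= fdr and
#' log2fc < 0; unchanged: padj > unchanged_padj and
#' -unchanged_abs_lfc < log2fc < unchanged_abs_lfc; everything else is
#' ambiguous. NA inputs give NA classes (genes excluded upstream).
#'
#' @param padj adjusted p-values.
#' @param log2fc log2 fold changes.
#' @param config an [analysis_config()].
#' @return character vector of class labels.
#' @export
classify_genes <- function(padj, log2fc, config = analysis_config()) {
  cls <- rep("ambiguous", length(padj))
  cls[padj <= config$de_fdr & log2fc > 0] <- "activated"
  cls[padj <= config$de_fdr & log2fc < 0] <- "repressed"
  cls[padj > config$unchanged_padj &
        log2fc > -config$unchanged_abs_lfc &
        log2fc < config$unchanged_abs_lfc] <- "unchanged"
  cls[is.na(padj) | is.na(log2fc)] <- NA_character_
  cls
}

#' Differential transcription test over a count matrix
#'
#' Runs the NB Wald test per gene with externally supplied size factors,
#' BH adjustment and class labels. By default the Wald variance uses a
#' dispersion pooled across genes (the mean of the per-gene
#' method-of-moments estimates): with few replicates a per-gene 2-df
#' plug-in makes the normal-reference Wald statistic strongly
#' anti-conservative, while the pooled estimate restores calibration;
#' `dispersion = "per_gene"` keeps the plug-in behavior.
#'
#' @param counts genes x libraries integer matrix (rownames = gene ids).
#' @param size_factors numeric per library.
#' @param conditions condition labels per library.
#' @param config an [analysis_config()].
#' @param reference baseline condition.
#' @param dispersion "pooled" or "per_gene".
#' @return data.frame: gene_id, mean_norm, log2fc, alpha, p, padj, class.
#' @export
differential_test <- function(counts, size_factors, conditions,
                              config = analysis_config(), reference = "NHS",
                              dispersion = c("pooled", "per_gene")) {
  dispersion <- match.arg(dispersion)
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == length(size_factors),
            ncol(counts) == length(conditions))
  n <- nrow(counts)
  alpha_hat <- vapply(seq_len(n), function(i) {
    estimate_dispersion(counts[i, ], size_factors, conditions)
  }, numeric(1))
  alpha_use <- if (dispersion == "pooled") {
    rep(mean(alpha_hat, na.rm = TRUE), n)
  } else {
    alpha_hat
  }
  res <- lapply(seq_len(n), function(i) {
    if (is.na(alpha_hat[i])) {
      return(list(log2fc = NA_real_, p = NA_real_, mean_norm = 0))
    }
    nb_wald_test(counts[i, ], size_factors, conditions, alpha_use[i],
                 reference = reference)
  })
  out <- data.frame(
    gene_id = rownames(counts) %||% paste0("g", seq_len(n)),
    mean_norm = vapply(res, `[[`, numeric(1), "mean_norm"),
    log2fc = vapply(res, `[[`, numeric(1), "log2fc"),
    alpha = alpha_use,
    p = vapply(res, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE)
  out$alpha[is.na(alpha_hat)] <- NA_real_
  out$padj <- bh_adjust(out$p)
  out$class <- classify_genes(out$padj, out$log2fc, config)
  out
}

#' Collect gene-body counts for differential analysis
#'
#' Builds the genes x libraries count matrix for one t-vs-NHS contrast.
#' The same elongation-capped window - `[+200, min(L, 1000 t))` for a
#' t-minute time point - is applied to every library of the contrast, so
#' counts are comparable between conditions. Genes whose capped window is
#' empty are excluded with a reason code.
#'
#' @param tracks named list of [signal_track()] per library.
#' @param genes gene table.
#' @param t_minutes the heat-shock time of the contrast (0 for NHS-only).
#' @param config an [analysis_config()].
#' @return list(counts = matrix, excluded = data.frame(gene_id, reason)).
#' @export
body_count_matrix <- function(tracks, genes, t_minutes = 0,
                              config = analysis_config()) {
  n <- nrow(genes)
  counts <- matrix(0, n, length(tracks),
                   dimnames = list(genes$gene_id, names(tracks)))
  excluded <- rep(FALSE, n)
  for (i in seq_len(n)) {
    g <- genes[i, ]
    w <- gene_body_window(g, t_minutes, config$body_offset,
                          config$elongation_rate)
    if (is.null(w)) { excluded[i] <- TRUE; next }
    for (j in seq_along(tracks)) {
      counts[i, j] <- count_window(tracks[[j]], g, w)$reads
    }
  }
  list(counts = counts[!excluded, , drop = FALSE],
       excluded = data.frame(gene_id = genes$gene_id[excluded],
                             reason = rep("empty_body_window",
                                          sum(excluded)),
                             stringsAsFactors = FALSE))
}
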