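#' Scenario configuration for the synthetic PRO-seq generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' sharply paused genes (a 3'-end peak 20-60 bp downstream of the TSS),
#' uniform gene-body signal, low antisense background, run-through
#' transcription bleeding from an upstream gene across the intergenic gap
#' into a downstream victim, per-library sequencing-depth scale factors,
#' and heat-shock activation/repression restricted to the
#' elongation-limited front of the gene body.
#'
#' Defaults are the package's study conditions: 2 chromosomes, 2000
#' non-overlapping genes, 5% activated at 8-fold, 15% repressed at 3-fold,
#' pause strengths of 50-300 expected reads, body rates of 50-200 reads/kb,
#' and a negative-binomial dispersion of 0.005 reflecting tightly
#' correlated replicate libraries.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_genes number of genes.
#' @param gene_length_range,intergenic_gap_range bp ranges (min, max).
#' @param frac_activated,frac_repressed class proportions; their sum must
#'   be < 1.
#' @param activation_fc_range,repression_fc_range fold-change ranges; the
#'   true HS/NHS fold change is drawn uniformly in the activation range for
#'   activated genes and as 1/x, x uniform in the repression range, for
#'   repressed genes.
#' @param pause_strength_range expected pause-region reads per gene (at
#'   scale factor 1).
#' @param body_rate_range expected gene-body reads per kb.
#' @param antisense_rate expected antisense reads per kb of gene span.
#' @param runthrough_frac proportion of genes that are run-through victims
#'   of an upstream activated neighbor.
#' @param runthrough_decay per-bp geometric decay of run-through signal.
#' @param chip_high_frac proportion of genes in the high mode of the Ser2-P
#'   style ChIP signal (placed on unchanged genes: the constitutive,
#'   invariant fraction of the transcriptome).
#' @param chip_high_mult multiplier separating the high ChIP mode.
#' @param nb_dispersion negative-binomial dispersion alpha (variance
#'   m + alpha m^2).
#' @param hs_time_minutes heat-shock duration used by the default design.
#' @param library_scale_factors one positive depth multiplier per library
#'   (default design: two NHS then two HS libraries).
#' @param seed integer seed; all generator output is a pure function of the
#'   configuration including this seed.
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_chromosomes = 2,
                            chrom_length = 6.5e6,
                            n_genes = 2000,
                            gene_length_range = c(2000, 8000),
                            intergenic_gap_range = c(500, 2000),
                            frac_activated = 0.05,
                            frac_repressed = 0.15,
                            activation_fc_range = c(8, 8),
                            repression_fc_range = c(3, 3),
                            pause_strength_range = c(50, 300),
                            body_rate_range = c(50, 200),
                            antisense_rate = 2,
                            runthrough_frac = 0,
                            runthrough_decay = 0.9997,
                            chip_high_frac = 0.05,
                            chip_high_mult = 300,
                            nb_dispersion = 0.005,
                            hs_time_minutes = 20,
                            library_scale_factors = c(1.0, 1.3, 0.8, 1.1),
                            seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_chromosomes >= 1, chrom_length > 0, n_genes >= 0,
            frac_activated >= 0, frac_repressed >= 0,
            frac_activated + frac_repressed < 1,
            all(gene_length_range > 0), all(intergenic_gap_range >= 0),
            all(activation_fc_range >= 1), all(repression_fc_range >= 1),
            all(pause_strength_range >= 0), all(body_rate_range >= 0),
            antisense_rate >= 0, runthrough_frac >= 0, runthrough_frac <= 1,
            runthrough_decay > 0, runthrough_decay < 1,
            nb_dispersion >= 0, all(library_scale_factors > 0),
            hs_time_minutes > 0)
  class(cfg) <- "scenario_config"
  cfg
}

#' Generate a genome layout, gene annotation and ground truth
#'
#' Genes are tiled left to right with intergenic gaps drawn from the
#' configured range, moving to the next chromosome when a gene no longer
#' fits. Classes are assigned by stratified sampling; run-through victims
#' are placed immediately downstream of an activated source gene on the
#' plus strand so that the source's read-through signal decays across the
#' gap into the victim. The truth table records everything needed to score
#' the analysis: class, true fold change, pause strength, body rate, ChIP
#' signal and run-through status per gene.
#'
#' @param config a [scenario_config()].
#' @return list with elements `config`, `chrom_sizes` (named vector),
#'   `genes` (gene table) and `truth` (data.frame keyed by gene_id).
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  n <- config$n_genes
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  chrom_sizes <- stats::setNames(rep(as.integer(config$chrom_length),
                                     config$n_chromosomes), chroms)
  if (n == 0) {
    genes <- gene_table(character(), character(), integer(), integer(),
                        character())
    truth <- data.frame(gene_id = character(), class = character(),
                        true_fc = numeric(), pause_reads = numeric(),
                        body_rate = numeric(), chip_high = logical(),
                        chip_signal = numeric(),
                        runthrough_victim = logical(),
                        runthrough_source = character(),
                        stringsAsFactors = FALSE)
    return(list(config = config, chrom_sizes = chrom_sizes, genes = genes,
                truth = truth))
  }
  set.seed(derive_seed(config$seed, 0))

  lens <- round(stats::runif(n, config$gene_length_range[1],
                             config$gene_length_range[2]))
  gaps <- round(stats::runif(n, config$intergenic_gap_range[1],
                             config$intergenic_gap_range[2]))
  chrom <- character(n); start <- integer(n)
  ci <- 1L; cur <- gaps[1]
  for (i in seq_len(n)) {
    if (cur + lens[i] > chrom_sizes[ci]) {
      ci <- ci + 1L
      if (ci > config$n_chromosomes) {
        stop("infeasible packing: genes do not fit in the configured genome")
      }
      cur <- gaps[i]
    }
    chrom[i] <- chroms[ci]
    start[i] <- as.integer(cur)
    cur <- cur + lens[i] + gaps[i]
  }
  end <- start + as.integer(lens)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  gene_id <- sprintf("g%04d", seq_len(n))

  # run-through pairs: victim i preceded on the same chromosome by source
  # i-1; both forced to the plus strand so transcription runs into the victim
  n_rt <- round(config$runthrough_frac * n)
  victim <- rep(FALSE, n); source_of <- rep(NA_character_, n)
  if (n_rt > 0) {
    eligible <- which(seq_len(n) > 1 & chrom == c("", chrom[-n]))
    picked <- integer(0)
    for (i in sample(eligible)) {
      if (length(picked) >= n_rt) break
      if ((i - 1) %in% picked || (i + 1) %in% picked || i %in% (picked - 1)) next
      picked <- c(picked, i)
    }
    if (length(picked) < n_rt) {
      stop("cannot place the requested number of run-through pairs")
    }
    victim[picked] <- TRUE
    source_of[picked] <- gene_id[picked - 1]
    strand[picked] <- "+"; strand[picked - 1] <- "+"
  }
  sources <- which(gene_id %in% source_of[victim])

  n_act <- round(config$frac_activated * n)
  n_rep <- round(config$frac_repressed * n)
  if (length(sources) > n_act) {
    stop("runthrough_frac requires more activated source genes than ",
         "frac_activated allows")
  }
  cls <- rep("unchanged", n)
  free <- setdiff(seq_len(n), c(sources, which(victim)))
  extra_act <- sample(free, n_act - length(sources))
  cls[c(sources, extra_act)] <- "activated"
  free <- setdiff(free, extra_act)
  cls[sample(free, n_rep)] <- "repressed"

  true_fc <- rep(1, n)
  ia <- cls == "activated"; ir <- cls == "repressed"
  true_fc[ia] <- stats::runif(sum(ia), config$activation_fc_range[1],
                              config$activation_fc_range[2])
  true_fc[ir] <- 1 / stats::runif(sum(ir), config$repression_fc_range[1],
                                  config$repression_fc_range[2])

  body_rate <- stats::runif(n, config$body_rate_range[1],
                            config$body_rate_range[2])
  pause_reads <- stats::runif(n, config$pause_strength_range[1],
                              config$pause_strength_range[2])

  # Ser2-P style ChIP signal: broad lognormal bulk with a strongly
  # separated high mode on constitutively transcribed (unchanged) genes
  chip_high <- rep(FALSE, n)
  n_high <- round(config$chip_high_frac * n)
  unch <- which(cls == "unchanged")
  if (n_high > length(unch)) {
    stop("chip_high_frac exceeds the available unchanged genes")
  }
  chip_high[sample(unch, n_high)] <- TRUE
  chip_signal <- body_rate * exp(stats::rnorm(n, 0, 0.46)) *
    ifelse(chip_high, config$chip_high_mult, 1)

  genes <- gene_table(gene_id, chrom, start, end, strand)
  truth <- data.frame(gene_id = gene_id, class = cls, true_fc = true_fc,
                      pause_reads = pause_reads, body_rate = body_rate,
                      chip_high = chip_high, chip_signal = chip_signal,
                      runthrough_victim = victim,
                      runthrough_source = source_of,
                      stringsAsFactors = FALSE)
  truth <- truth[match(genes$gene_id, truth$gene_id), , drop = FALSE]
  rownames(truth) <- NULL
  list(config = config, chrom_sizes = chrom_sizes, genes = genes,
       truth = truth)
}

#' Default library design for a scenario
#'
#' Two NHS and two HS libraries with the configured scale factors and
#' heat-shock time.
#'
#' @param config a [scenario_config()].
#' @return data.frame with columns library_index, condition, t_minutes,
#'   scale_factor.
#' @export
default_design <- function(config) {
  sf <- config$library_scale_factors
  n_lib <- length(sf)
  stopifnot(n_lib >= 2, n_lib %% 2 == 0)
  half <- n_lib / 2
  data.frame(library_index = seq_len(n_lib),
             condition = rep(c("NHS", "HS"), each = half),
             t_minutes = rep(c(0, config$hs_time_minutes), each = half),
             scale_factor = sf, stringsAsFactors = FALSE)
}

.rnb <- function(n, mu, alpha) {
  mu <- pmax(mu, 0)
  if (alpha <= 1e-12) return(stats::rpois(n, mu))
  stats::rnbinom(n, mu = mu, size = 1 / alpha)
}

#' Simulate one PRO-seq library as a signal track
#'
#' Expected counts follow the generative model: pause-region reads are
#' placed on a discretized triangular distribution over TSS offsets
#' +20..+60 peaking at +35; gene-body reads are uniform over
#' `[TSS+200, end)`; heat shock multiplies the body rate by the gene's true
#' fold change only within the elongation-limited front
#' `[TSS+200, TSS + 1000 * t)`; antisense reads fall uniformly on the
#' opposite strand across the span; run-through victims additionally
#' receive the source gene's body signal decaying geometrically from the
#' source's 3' end across the gap and through the victim. All counts are
#' negative-binomial with the configured dispersion and scaled by the
#' library's depth factor.
#'
#' @param scenario output of [generate_scenario()].
#' @param condition "NHS" or "HS".
#' @param t_minutes heat-shock minutes (ignored for NHS).
#' @param scale_factor library depth multiplier.
#' @param library_index integer label; also selects the random stream.
#' @param seed optional explicit seed; defaults to a stream derived from
#'   the scenario seed and `library_index`.
#' @return A [signal_track()] with a `deposited` attribute (per-gene ledger
#'   of sense, antisense and run-through reads placed).
#' @export
simulate_library <- function(scenario, condition = c("NHS", "HS"),
                             t_minutes = 0, scale_factor = 1,
                             library_index = 1, seed = NULL) {
  condition <- match.arg(condition)
  cfg <- scenario$config
  genes <- scenario$genes
  truth <- scenario$truth
  set.seed(seed %||% derive_seed(cfg$seed, library_index))
  alpha <- cfg$nb_dispersion
  hs <- condition == "HS"
  front <- if (hs) 1000 * t_minutes else Inf

  n <- nrow(genes)
  chrom_l <- pos_l <- cnt_l <- strand_l <- vector("list", 3 * max(n, 1))
  k <- 0L
  ledger <- data.frame(gene_id = genes$gene_id, sense = 0, antisense = 0,
                       runthrough = 0)
  add <- function(chrom, strand, pos, counts = NULL) {
    if (length(pos) == 0) return(invisible(0))
    k <<- k + 1L
    chrom_l[[k]] <<- rep(chrom, length(pos))
    strand_l[[k]] <<- rep(strand, length(pos))
    pos_l[[k]] <<- pos
    cnt_l[[k]] <<- if (is.null(counts)) rep(1, length(pos)) else counts
    invisible(length(pos))
  }
  pause_off <- 20:60
  pause_w <- ifelse(pause_off <= 35, (pause_off - 20) / 15,
                    (60 - pause_off) / 25)

  for (i in seq_len(n)) {
    g <- genes[i, ]
    tr <- truth[i, ]
    len <- g$end - g$start
    dirn <- if (g$strand == "+") 1L else -1L
    anti_strand <- if (g$strand == "+") "-" else "+"

    # pause peak (unaffected by HS)
    n_pause <- .rnb(1, scale_factor * tr$pause_reads, alpha)
    if (n_pause > 0) {
      off <- sample(pause_off, n_pause, replace = TRUE, prob = pause_w)
      add(g$chrom, g$strand, g$tss + dirn * off)
      ledger$sense[i] <- ledger$sense[i] + n_pause
    }

    # gene body, split at the elongation front for HS
    rate_bp <- tr$body_rate / 1000
    segs <- if (!hs || front >= len) {
      list(c(200, len, if (hs) tr$true_fc else 1))
    } else if (front <= 200) {
      list(c(200, len, 1))
    } else {
      list(c(200, front, tr$true_fc), c(front, len, 1))
    }
    for (sg in segs) {
      w <- sg[2] - sg[1]
      if (w <= 0) next
      nb <- .rnb(1, scale_factor * rate_bp * w * sg[3], alpha)
      if (nb > 0) {
        off <- sg[1] + sample.int(w, nb, replace = TRUE) - 1L
        add(g$chrom, g$strand, g$tss + dirn * off)
        ledger$sense[i] <- ledger$sense[i] + nb
      }
    }

    # antisense background over the span
    na <- .rnb(1, scale_factor * cfg$antisense_rate / 1000 * len, alpha)
    if (na > 0) {
      add(g$chrom, anti_strand,
          g$start + sample.int(len, na, replace = TRUE) - 1L)
      ledger$antisense[i] <- na
    }

    # run-through from the upstream source across the gap into the victim
    if (isTRUE(tr$runthrough_victim)) {
      src_g <- genes[genes$gene_id == tr$runthrough_source, ]
      src_t <- truth[truth$gene_id == tr$runthrough_source, ]
      fc_src <- if (hs && front > src_g$end - src_g$start) src_t$true_fc else 1
      a0 <- scale_factor * src_t$body_rate / 1000 * fc_src
      width <- g$end - src_g$end
      dec <- cfg$runthrough_decay^(0:(width - 1))
      nr <- .rnb(1, a0 * sum(dec), alpha)
      if (nr > 0) {
        d <- sample.int(width, nr, replace = TRUE, prob = dec) - 1L
        add(g$chrom, "+", src_g$end + d)
        ledger$runthrough[i] <- nr
      }
    }
  }
  track <- signal_track(unlist(chrom_l[seq_len(k)]),
                        unlist(strand_l[seq_len(k)]),
                        unlist(pos_l[seq_len(k)]),
                        unlist(cnt_l[seq_len(k)]),
                        chrom_sizes = scenario$chrom_sizes)
  attr(track, "deposited") <- ledger
  track
}

#' Simulate every library of a design
#'
#' @param scenario output of [generate_scenario()].
#' @param design a design data.frame as from [default_design()].
#' @return list(tracks = list of signal_track keyed "lib<i>", design).
#' @export
simulate_experiment <- function(scenario, design = NULL) {
  design <- design %||% default_design(scenario$config)
  tracks <- lapply(seq_len(nrow(design)), function(i) {
    simulate_library(scenario, condition = design$condition[i],
                     t_minutes = design$t_minutes[i],
                     scale_factor = design$scale_factor[i],
                     library_index = design$library_index[i])
  })
  names(tracks) <- paste0("lib", design$library_index)
  list(tracks = tracks, design = design)
}

#' Simulate ChIP peak sets for the scenario
#'
#' Places a peak near the TSS of a fraction of genes in the target classes
#' (emulating a factor bound at those promoters) plus unlinked background
#' peaks at random intergenic positions.
#'
#' @param scenario output of [generate_scenario()].
#' @param target_classes character classes whose genes the factor binds.
#' @param frac_bound fraction of target genes receiving a peak.
#' @param jitter maximal |offset| of the peak center from the TSS.
#' @param peak_width peak width in bp.
#' @param n_background number of background peaks.
#' @param seed random stream seed offset.
#' @return Interval data.frame (chrom, start, end, score).
#' @export
simulate_peaks <- function(scenario, target_classes = "activated",
                           frac_bound = 0.9, jitter = 300, peak_width = 300,
                           n_background = 50, seed = 1000) {
  set.seed(derive_seed(scenario$config$seed, seed))
  genes <- scenario$genes
  targets <- genes[scenario$truth$class[match(genes$gene_id,
                                              scenario$truth$gene_id)] %in%
                     target_classes, , drop = FALSE]
  n_t <- round(frac_bound * nrow(targets))
  bound <- targets[sample(nrow(targets), n_t), , drop = FALSE]
  center <- bound$tss + round(stats::runif(n_t, -jitter, jitter))
  bg_chrom <- sample(names(scenario$chrom_sizes), n_background, replace = TRUE)
  bg_center <- round(stats::runif(n_background, peak_width,
                                  scenario$chrom_sizes[bg_chrom] - peak_width))
  out <- data.frame(
    chrom = c(bound$chrom, bg_chrom),
    start = as.integer(c(center, bg_center) - peak_width %/% 2),
    end = as.integer(c(center, bg_center) + peak_width %/% 2),
    score = round(stats::rlnorm(n_t + n_background, 3, 0.5), 2),
    stringsAsFactors = FALSE)
  out$start <- pmax(out$start, 0L)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Write a simulated scenario to plain-text fixture files
#'
#' Writes one plus- and one minus-strand bedGraph per library, the gene
#' annotation (BED6), a full-genome mappability track (BED3), the truth
#' table and the design (TSV), and any peak sets (BED5). Files round-trip
#' losslessly through the package readers.
#'
#' @param scenario output of [generate_scenario()].
#' @param experiment output of [simulate_experiment()].
#' @param out_dir output directory (created if needed).
#' @param peaks optional named list of peak interval data.frames.
#' @return data.frame manifest (type, name, path).
#' @export
emit_fixture_files <- function(scenario, experiment, out_dir, peaks = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  put <- function(type, name, path) {
    manifest[[length(manifest) + 1]] <<- data.frame(type = type, name = name,
                                                    path = path)
  }
  design <- experiment$design
  for (i in seq_len(nrow(design))) {
    lib <- design$library_index[i]
    base <- sprintf("lib%d_%s", lib, design$condition[i])
    pp <- file.path(out_dir, paste0(base, "_plus.bedgraph"))
    mp <- file.path(out_dir, paste0(base, "_minus.bedgraph"))
    write_bedgraph(experiment$tracks[[paste0("lib", lib)]], pp, mp)
    put("bedgraph_plus", base, pp)
    put("bedgraph_minus", base, mp)
  }
  gp <- file.path(out_dir, "genes.bed")
  write_bed(scenario$genes, gp)
  put("genes", "genes", gp)
  mp <- file.path(out_dir, "mappability.bed")
  write_bed(data.frame(chrom = names(scenario$chrom_sizes), start = 0L,
                       end = as.integer(scenario$chrom_sizes),
                       score = NA_real_), mp)
  put("mappability", "mappability", mp)
  tp <- file.path(out_dir, "truth.tsv")
  utils::write.table(scenario$truth, tp, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  put("truth", "truth", tp)
  dp <- file.path(out_dir, "design.tsv")
  utils::write.table(design, dp, quote = FALSE, sep = "\t", row.names = FALSE)
  put("design", "design", dp)
  for (nm in names(peaks)) {
    pp <- file.path(out_dir, paste0("peaks_", nm, ".bed"))
    write_bed(peaks[[nm]], pp)
    put("peaks", nm, pp)
  }
  do.call(rbind, manifest)
}
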