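test_that("empty scenario gives empty genes and truth", {
  sc <- generate_scenario(scenario_config(n_genes = 0))
  expect_equal(nrow(sc$genes), 0)
  expect_equal(nrow(sc$truth), 0)
})

test_that("scenario generation is deterministic in the seed", {
  cfg <- scenario_config(n_genes = 120, chrom_length = 8e5,
                         runthrough_frac = 0.02, seed = 9)
  sc1 <- generate_scenario(cfg)
  sc2 <- generate_scenario(cfg)
  expect_identical(sc1, sc2)
  tr1 <- simulate_library(sc1, "HS", 20, 1.2, library_index = 3)
  tr2 <- simulate_library(sc2, "HS", 20, 1.2, library_index = 3)
  expect_identical(tr1$data, tr2$data)
  sc3 <- generate_scenario(scenario_config(n_genes = 120,
                                           chrom_length = 8e5,
                                           runthrough_frac = 0.02,
                                           seed = 10))
  expect_false(identical(sc1$genes, sc3$genes))
})

test_that("class labels follow the configured proportions", {
  sc <- generate_scenario(scenario_config(n_genes = 1000,
                                          chrom_length = 4e6,
                                          frac_activated = 0.05,
                                          frac_repressed = 0.15))
  expect_equal(sum(sc$truth$class == "activated"), 50)
  expect_equal(sum(sc$truth$class == "repressed"), 150)
  expect_true(all(sc$truth$true_fc[sc$truth$class == "unchanged"] == 1))
})

test_that("gene spans never overlap and packing failures raise", {
  sc <- generate_scenario(scenario_config(n_genes = 300,
                                          chrom_length = 1.5e6))
  g <- sc$genes
  for (ch in unique(g$chrom)) {
    gc <- g[g$chrom == ch, ]
    expect_true(all(gc$start[-1] >= gc$end[-nrow(gc)]))
  }
  expect_error(generate_scenario(scenario_config(n_genes = 300,
                                                 chrom_length = 1e5)),
               "packing")
})

test_that("zero scale factor produces an all-zero track", {
  sc <- generate_scenario(scenario_config(n_genes = 20,
                                          chrom_length = 3e5,
                                          antisense_rate = 0))
  tr <- simulate_library(sc, "NHS", scale_factor = 1e-12)
  expect_equal(track_total(tr), 0)
})

test_that("simulated counts match their closed-form expectations", {
  # large rates, many genes: sample mean within 3 SE of the model mean
  cfg <- scenario_config(n_genes = 1000, chrom_length = 4e6,
                         gene_length_range = c(4000, 4000),
                         body_rate_range = c(100, 100),
                         pause_strength_range = c(200, 200),
                         frac_activated = 0, frac_repressed = 0,
                         antisense_rate = 5, nb_dispersion = 0.005,
                         seed = 21)
  sc <- generate_scenario(cfg)
  sf <- 1.3
  tr <- simulate_library(sc, "NHS", scale_factor = sf)
  led <- attr(tr, "deposited")
  n <- nrow(sc$genes)
  # pause region expectation: scale * pause_reads
  m_pause <- sf * 200
  se_pause <- sqrt((m_pause + 0.005 * m_pause^2) / n)
  pause_counts <- vapply(seq_len(n), function(i) {
    count_window(tr, sc$genes[i, ], relative_window(0, 100))$reads
  }, numeric(1))
  expect_lt(abs(mean(pause_counts) - m_pause), 3 * se_pause)
  # body expectation: scale * rate_per_kb * body_kb
  m_body <- sf * 100 * 3.8
  se_body <- sqrt((m_body + 0.005 * m_body^2) / n)
  body_counts <- vapply(seq_len(n), function(i) {
    count_window(tr, sc$genes[i, ], relative_window(200, 4000))$reads
  }, numeric(1))
  expect_lt(abs(mean(body_counts) - m_body), 3 * se_body)
  # antisense expectation: scale * rate_per_kb * span_kb
  m_anti <- sf * 5 * 4
  expect_lt(abs(mean(led$antisense) - m_anti),
            3 * sqrt((m_anti + 0.005 * m_anti^2) / n))
})

test_that("activation scales the body by the true fold change", {
  cfg <- scenario_config(n_genes = 1000, chrom_length = 7e6,
                         gene_length_range = c(5000, 5000),
                         body_rate_range = c(100, 100),
                         frac_activated = 0.999, frac_repressed = 0,
                         activation_fc_range = c(8, 8),
                         nb_dispersion = 0.005, antisense_rate = 0,
                         chip_high_frac = 0, seed = 22)
  sc <- generate_scenario(cfg)
  act <- sc$truth$class == "activated"
  nhs <- simulate_library(sc, "NHS", library_index = 1)
  hs <- simulate_library(sc, "HS", t_minutes = 20, library_index = 2)
  w <- relative_window(200, 5000)
  r <- vapply(which(act), function(i) {
    count_window(hs, sc$genes[i, ], w)$reads /
      count_window(nhs, sc$genes[i, ], w)$reads
  }, numeric(1))
  # 5 kb gene < 20 kb elongation front: the whole body is amplified 8x
  expect_lt(abs(mean(r) - 8), 3 * stats::sd(r) / sqrt(length(r)))
  # at t = 2 min only [200, 2000) is amplified
  hs2 <- simulate_library(sc, "HS", t_minutes = 2, library_index = 3)
  r_front <- mean(vapply(which(act), function(i) {
    count_window(hs2, sc$genes[i, ], relative_window(200, 2000))$reads
  }, numeric(1)))
  r_past <- mean(vapply(which(act), function(i) {
    count_window(hs2, sc$genes[i, ], relative_window(2000, 5000))$reads
  }, numeric(1)))
  expect_gt(r_front / (0.1 * 1800), 6)   # amplified segment
  expect_lt(r_past / (0.1 * 3000), 1.5)  # untouched past the front
})

test_that("deposited reads are conserved in the track", {
  cfg <- scenario_config(n_genes = 150, chrom_length = 8e5,
                         runthrough_frac = 0.04, seed = 5)
  sc <- generate_scenario(cfg)
  for (cond in c("NHS", "HS")) {
    tr <- simulate_library(sc, cond, t_minutes = 20, scale_factor = 1.1)
    led <- attr(tr, "deposited")
    expect_equal(track_total(tr),
                 sum(led$sense + led$antisense + led$runthrough))
  }
})

test_that("run-through victims receive decaying upstream signal", {
  cfg <- scenario_config(n_genes = 200, chrom_length = 1.5e6,
                         runthrough_frac = 0.05, seed = 6)
  sc <- generate_scenario(cfg)
  v <- sc$truth$runthrough_victim
  expect_equal(sum(v), 10)
  # sources are activated, victims unchanged, both plus-strand, adjacent
  src_ids <- sc$truth$runthrough_source[v]
  src <- sc$truth[match(src_ids, sc$truth$gene_id), ]
  expect_true(all(src$class == "activated"))
  expect_true(all(sc$truth$class[v] == "unchanged"))
  hs <- simulate_library(sc, "HS", t_minutes = 20)
  led <- attr(hs, "deposited")
  expect_true(all(led$runthrough[v] > 0))
  expect_true(all(led$runthrough[!v] == 0))
  # upstream window of a victim sees the source's read-through
  vi <- which(v)[1]
  up <- count_window(hs, sc$genes[vi, ], relative_window(-500, -100))$reads
  expect_gt(up, 0)
})

test_that("fixture files round-trip through the readers", {
  cfg <- scenario_config(n_genes = 40, chrom_length = 4e5,
                         library_scale_factors = c(1, 0.9), seed = 8)
  sc <- generate_scenario(cfg)
  ex <- simulate_experiment(sc)
  peaks <- simulate_peaks(sc, n_background = 5)
  out <- withr::local_tempdir()
  man <- emit_fixture_files(sc, ex, out, peaks = list(hsf = peaks))
  expect_equal(sum(man$type == "bedgraph_plus"), 2)
  expect_equal(sum(man$type == "bedgraph_minus"), 2)
  tr <- read_bedgraph_pair(man$path[man$type == "bedgraph_plus"][1],
                           man$path[man$type == "bedgraph_minus"][1],
                           chrom_sizes = sc$chrom_sizes)
  expect_equal(as.data.frame(tr$data),
               as.data.frame(ex$tracks[[1]]$data))
  genes <- read_genes(man$path[man$type == "genes"])
  expect_equal(genes, sc$genes, ignore_attr = TRUE)
  pk <- read_intervals(man$path[man$type == "peaks"])
  expect_equal(pk$start, peaks$start[order(peaks$chrom, peaks$start)])
})
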