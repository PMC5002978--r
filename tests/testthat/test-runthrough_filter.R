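test_that("upstream ratio is a density ratio with mappability adjustment", {
  g <- one_gene("+", start = 10000, end = 15000)
  # 2 reads upstream, 40 in the body window: (2/400)/(40/400) = 0.05
  tr <- pool_tracks(list(
    rel_track(g, c(-400, -300)),
    rel_track(g, round(seq(310, 690, length.out = 40)))))
  expect_equal(upstream_ratio(tr, g)$ratio, 0.05)
  # no upstream reads -> 0
  tr0 <- rel_track(g, round(seq(310, 690, length.out = 40)))
  expect_equal(upstream_ratio(tr0, g)$ratio, 0)
  # half the upstream window unmappable: 2 reads / 200 mappable bases
  # against body density 0.1/base -> 0.1
  mapp <- data.frame(chrom = "chr1",
                     start = c(g$tss - 300, g$tss + 300),
                     end = c(g$tss - 100, g$tss + 700))
  tr2 <- pool_tracks(list(
    rel_track(g, c(-290, -280)),
    rel_track(g, round(seq(310, 690, length.out = 40)))))
  expect_equal(upstream_ratio(tr2, g, mappability = mapp)$ratio, 0.1)
  # zero body signal -> undefined
  expect_true(is.na(upstream_ratio(rel_track(g, c(-300)), g)$ratio))
})

test_that("cutoff search maximizes accuracy with the smallest-cutoff tie", {
  res <- optimize_cutoff(c(0.05, 0.10, 0.50, 0.90),
                         c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(res$cutoff, 0.10)
  expect_equal(res$best_accuracy, 1)
  expect_true(all(res$accuracy[res$grid >= 0.10 & res$grid <= 0.49] == 1))
  # all genes true -> retain everything
  expect_equal(optimize_cutoff(c(0.2, 0.9, 1.0), rep(TRUE, 3))$cutoff, 1)
})

test_that("cutoff search equals brute-force grid maximization", {
  grid <- seq(0, 1, by = 0.01)
  brute <- function(r, lab) {
    acc <- sapply(grid, function(c) {
      (sum(lab & r <= c) + sum(!lab & r > c)) / length(r)
    })
    list(cutoff = grid[which.max(acc)], acc = max(acc))
  }
  set.seed(51)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    r <- round(stats::runif(n), 2)
    lab <- stats::runif(n) < 0.5
    if (!any(lab) || all(lab)) next
    got <- optimize_cutoff(r, lab)
    want <- brute(r, lab)
    expect_identical(got$cutoff, want$cutoff)
    expect_identical(got$best_accuracy, want$acc)
  }
  # perfectly interleaved ratios bound the attainable accuracy
  n <- 10
  r <- seq(0.05, 0.95, length.out = 2 * n)
  lab <- rep(c(TRUE, FALSE), n)
  expect_lte(optimize_cutoff(r, lab)$best_accuracy, (n + 1) / (2 * n))
})

test_that("the filter removes by condition-matched ratio with > cutoff", {
  classes <- data.frame(
    gene_id = c("a", "b", "c", "d", "e"),
    class = c("activated", "activated", "repressed", "unchanged",
              "activated"),
    stringsAsFactors = FALSE)
  r_hs <- c(a = 0.30, b = 0.23, c = 0.90, d = 0.90, e = NA)
  r_nhs <- c(a = 0.01, b = 0.01, c = 0.10, d = 0.90, e = 0.9)
  res <- apply_runthrough_filter(classes, r_nhs, r_hs, cutoff = 0.23)
  out <- res$classes
  # activated filtered on the HS ratio; 0.30 removed, 0.23 retained
  expect_equal(out$filtered_class[out$gene_id == "a"],
               "removed_runthrough")
  expect_equal(out$filtered_class[out$gene_id == "b"], "activated")
  # repressed filtered on the NHS ratio (0.10 retained despite HS 0.90)
  expect_equal(out$filtered_class[out$gene_id == "c"], "repressed")
  # unchanged genes are never filtered
  expect_equal(out$filtered_class[out$gene_id == "d"], "unchanged")
  # missing ratio -> retained and flagged
  expect_equal(out$filtered_class[out$gene_id == "e"], "activated")
  expect_true(out$ratio_missing[out$gene_id == "e"])
  expect_equal(res$audit$filter_condition[res$audit$gene_id == "a"], "HS")
  expect_equal(res$audit$filter_condition[res$audit$gene_id == "c"], "NHS")
})

test_that("run-through artifacts are filtered while true calls survive", {
  cfg <- scenario_config(n_genes = 1000, chrom_length = 4e6,
                         frac_activated = 0.1, runthrough_frac = 0.025,
                         seed = 52)
  sc <- generate_scenario(cfg)
  ex <- simulate_experiment(sc)
  sel <- select_unchanged_genes(ex$tracks[1:2], ex$tracks[3:4], sc$genes,
                                sc$truth$chip_signal)
  sf <- compute_size_factors(ex$tracks, sc$genes, sel$unchanged)
  bc <- body_count_matrix(ex$tracks, sc$genes, 20)
  de <- differential_test(bc$counts, sf$size_factors, ex$design$condition)
  pool_nhs <- pool_tracks(ex$tracks[1:2])
  pool_hs <- pool_tracks(ex$tracks[3:4])
  r_nhs <- upstream_ratio_table(pool_nhs, sc$genes)
  r_hs <- upstream_ratio_table(pool_hs, sc$genes)
  filt <- apply_runthrough_filter(de[, c("gene_id", "class")], r_nhs, r_hs)
  out <- filt$classes
  truth <- sc$truth[match(out$gene_id, sc$truth$gene_id), ]
  victims_called <- truth$runthrough_victim & out$class == "activated"
  expect_gt(sum(victims_called), 10)  # the artifact is induced
  expect_gte(mean(out$removed[victims_called]), 0.9)
  true_act <- truth$class == "activated" & out$class == "activated"
  expect_lte(mean(out$removed[true_act]), 0.1)
})
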