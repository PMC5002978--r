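brute_distance <- function(peaks, gene) {
  pk <- peaks[peaks$chrom == gene$chrom, , drop = FALSE]
  if (nrow(pk) == 0) return(NA_real_)
  best <- Inf
  for (j in seq_len(nrow(pk))) {
    for (p in pk$start[j]:(pk$end[j] - 1)) {
      d <- p - gene$tss
      if (abs(d) < abs(best)) best <- d
    }
  }
  if (gene$strand == "-") best <- -best
  best
}

test_that("closest peak distance: overlap, sign and orientation", {
  peaks <- data.frame(chrom = "chr1", start = c(900, 1200),
                      end = c(1100, 1301))
  g <- gene_table("g", "chr1", 1000, 5000, "+")[1, ]
  expect_equal(closest_peak_distance(peaks, g), 0)
  far <- data.frame(chrom = "chr1", start = 1200, end = 1301)
  expect_equal(closest_peak_distance(far, g), 200)
  gm <- gene_table("g", "chr1", 10, 1001, "-")[1, ]  # TSS 1000
  expect_equal(closest_peak_distance(far, gm), -200)
  none <- data.frame(chrom = "chr9", start = 1, end = 2)
  expect_true(is.na(closest_peak_distance(none, g)))
})

test_that("closest peak distance equals all-pairs brute force", {
  set.seed(81)
  for (i in 1:40) {
    n_pk <- sample(1:8, 1)
    start <- sort(sample(0:3000, n_pk))
    peaks <- data.frame(chrom = "chr1", start = start,
                        end = start + sample(5:50, n_pk, TRUE))
    g <- gene_table("g", "chr1", 100, 4000,
                    sample(c("+", "-"), 1))[1, ]
    g2 <- g; g2$tss <- sample(0:3500, 1)
    expect_equal(closest_peak_distance(peaks, g2),
                 brute_distance(peaks, g2))
  }
})

test_that("bound calls use the inclusive 1 kb rule, monotone in max_dist", {
  genes <- gene_table(c("at0", "at1000", "at1001"), "chr1",
                      c(5000, 11000, 17051), c(9000, 15000, 20000), "+")
  peaks <- data.frame(chrom = "chr1", start = c(5000, 10000, 16000),
                      end = c(5050, 10001, 16050))
  # distances: 0 (inside), 1000 (tss 11000 vs peak end base 10000),
  # 1001 (tss 17051 vs peak end base 16049... constructed below)
  d <- peak_distance_table(peaks, genes)
  expect_equal(d$distance[d$gene_id == "at0"], 0)
  expect_equal(d$distance[d$gene_id == "at1000"], -1000)
  expect_equal(d$distance[d$gene_id == "at1001"], -1002)
  b <- bound_genes(peaks, genes, 1000)
  expect_setequal(b, c("at0", "at1000"))
  for (dist in c(0, 500, 1000, 1500)) {
    expect_true(all(bound_genes(peaks, genes, dist) %in%
                      bound_genes(peaks, genes, dist + 500)))
  }
})

test_that("distance CDF comparison matches a brute-force KS statistic", {
  expect_equal(distance_cdf_compare(c(1, 2, 5), c(1, 2, 5))$D, 0)
  expect_equal(distance_cdf_compare(c(1, 2), c(100, 200))$D, 1)
  set.seed(82)
  for (i in 1:25) {
    a <- sample(0:500, sample(5:30, 1), replace = TRUE)
    b <- sample(0:500, sample(5:30, 1), replace = TRUE)
    got <- distance_cdf_compare(a, b)$D
    grid <- sort(unique(c(a, b)))
    brute <- max(abs(stats::ecdf(a)(grid) - stats::ecdf(b)(grid)))
    expect_equal(got, brute)
  }
  expect_error(distance_cdf_compare(numeric(0), 1), "at least one")
})

test_that("enrichment screen: exact MWU example, ranking and flags", {
  sig <- cbind(f1 = c(10, 11, 12, 1, 2, 3),
               f2 = c(5, 6, 4, 5.5, 6.5, 4.4),
               const = rep(7, 6))
  rownames(sig) <- c("a1", "a2", "a3", "b1", "b2", "b3")
  scr <- enrichment_screen(sig, c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  f1 <- scr[scr$factor == "f1", ]
  # all A above all B: U = 9; exact two-sided p = 2/20
  expect_equal(f1$U, 9)
  expect_equal(f1$p, 0.1)
  expect_equal(f1$direction, 1)
  expect_true(scr$constant[scr$factor == "const"])
  expect_equal(scr$p[scr$factor == "const"], 1)
  expect_equal(scr$factor[1], "f1")  # ranked by ascending p
  # identical multisets: no enrichment signal
  same <- cbind(f = c(1, 2, 3, 1, 2, 3))
  rownames(same) <- rownames(sig)
  expect_gt(enrichment_screen(same, c("a1", "a2", "a3"),
                              c("b1", "b2", "b3"))$p, 0.9)
})

test_that("MWU p-value ranks match the reference implementation", {
  set.seed(83)
  sig <- matrix(stats::rlnorm(40 * 20), 40, 20,
                dimnames = list(sprintf("g%02d", 1:40),
                                sprintf("f%02d", 1:20)))
  a <- sprintf("g%02d", 1:15); b <- sprintf("g%02d", 21:40)
  scr <- enrichment_screen(sig, a, b)
  ref_p <- vapply(colnames(sig), function(f) {
    stats::wilcox.test(sig[a, f], sig[b, f])$p.value
  }, numeric(1))
  expect_equal(scr$factor, names(sort(ref_p)))
  expect_equal(scr$p, unname(sort(ref_p)))
})

test_that("promoter_signal sums the sense window per gene", {
  g <- one_gene("+")
  genes <- gene_table(g$gene_id, g$chrom, g$start, g$end, g$strand)
  tr <- rel_track(g, c(-700, -100, 0, 700, 800))
  ps <- promoter_signal(tr, genes, window = c(-750, 750))
  expect_equal(unname(ps), 4)  # +800 outside [-750, 750)
})
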