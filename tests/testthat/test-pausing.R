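brute_pause_window <- function(offsets, counts, lo = -50, hi = 150,
                               width = 50) {
  best_s <- NA_integer_; best <- -1
  for (s in lo:(hi - width)) {
    tot <- sum(counts[offsets >= s & offsets < s + width])
    if (tot > best) { best <- tot; best_s <- s }
  }
  best_s
}

test_that("pause window detection matches the worked cases", {
  g <- one_gene("+")
  # all reads at +30: most-upstream maximal window is [-19, +31)
  w <- find_pause_window(rel_track(g, rep(30, 5)), g)
  expect_equal(c(w$rel_start, w$rel_end), c(-19, 31))
  # zero signal: tie-break to the most upstream window [-50, 0)
  w0 <- find_pause_window(signal_track(), g)
  expect_equal(c(w0$rel_start, w0$rel_end), c(-50, 0))
})

test_that("pause window equals the exhaustive argmax on random profiles", {
  set.seed(61)
  for (i in 1:300) {
    strand <- sample(c("+", "-"), 1)
    g <- one_gene(strand)
    n <- sample(1:12, 1)
    offsets <- sample(-60:160, n)  # includes reads outside the search space
    counts <- sample(1:5, n, replace = TRUE)
    tr <- rel_track(g, offsets, counts)
    w <- find_pause_window(tr, g)
    inside <- offsets >= -50 & offsets < 150
    expect_equal(w$rel_start,
                 brute_pause_window(offsets[inside], counts[inside]))
  }
})

test_that("pausing index is a density ratio, scale-free", {
  pause <- list(reads = 100, mappable_bases = 50, density = 2)
  body <- list(reads = 200, mappable_bases = 1000, density = 0.2)
  expect_equal(pausing_index(pause, body), 10)
  expect_equal(pausing_index(body, body), 1)
  double <- function(x) list(reads = 2 * x$reads,
                             mappable_bases = x$mappable_bases,
                             density = 2 * x$density)
  expect_equal(pausing_index(double(pause), double(body)), 10)
  expect_true(is.na(pausing_index(pause, list(reads = 0,
                                              mappable_bases = 10,
                                              density = 0))))
})

test_that("paused_test equals the hypergeometric tail oracle", {
  hyper_tail <- function(pr, br, pm, bm) {
    # one-sided enrichment: P(X >= pr) for X ~ Hypergeom drawing
    # (pr + pm) items from pr+br reads and pm+bm bases
    k <- pr + pm
    sum(stats::dhyper(pr:min(k, pr + br), pr + br, pm + bm, k))
  }
  expect_equal(paused_test(0, 50, 50, 1000), 1)
  p <- paused_test(30, 10, 50, 1000)
  expect_lt(abs(p - hyper_tail(30, 10, 50, 1000)), 1e-9)
  set.seed(62)
  for (i in 1:200) {
    pr <- sample(0:40, 1); br <- sample(0:60, 1)
    pm <- sample(1:50, 1); bm <- sample(1:2000, 1)
    if (pr + br == 0) next
    expect_lt(abs(paused_test(pr, br, pm, bm) -
                    hyper_tail(pr, br, pm, bm)), 1e-9)
  }
})

test_that("uniform-density null genes are rarely called paused", {
  set.seed(63)
  n <- 3000
  called <- vapply(seq_len(n), function(i) {
    pm <- 50; bm <- 3800
    tot <- stats::rpois(1, 400)
    pr <- stats::rbinom(1, tot, pm / (pm + bm))
    paused_test(pr, tot - pr, pm, bm) <= 0.01
  }, logical(1))
  expect_lte(mean(called), 0.02)
})

test_that("windows are fixed in the reference and reused across conditions", {
  g <- one_gene("+")
  ref <- rel_track(g, rep(35, 20))             # NHS peak at +35
  other <- rel_track(g, rep(120, 50))          # HS signal elsewhere
  tab <- pausing_table(ref, list(NHS = ref, HS = other),
                       gene_table(g$gene_id, g$chrom, g$start, g$end,
                                  g$strand))
  expect_equal(tab$pause_start, -14)           # window fixed by NHS
  expect_equal(tab$pause_reads_NHS, 20)
  expect_equal(tab$pause_reads_HS, 0)          # +120 outside [-14, 36)
  expect_true(tab$paused_NHS)
  expect_false(tab$paused_HS)
})

test_that("pausing changes are recovered and label-swap antisymmetric", {
  set.seed(64)
  n <- 400
  genes <- gene_table(sprintf("g%03d", 1:n), "chr1",
                      (0:(n - 1)) * 10000 + 1000,
                      (0:(n - 1)) * 10000 + 6000, "+")
  lost <- 1:50  # five-fold pause loss after HS
  mk_lib <- function(cond) {
    pos <- integer(0)
    for (i in seq_len(n)) {
      mu <- if (cond == "HS" && i %in% lost) 40 else 200
      k <- stats::rnbinom(1, mu = mu, size = 1 / 0.005)
      p <- genes$tss[i] + sample(20:60, k, replace = TRUE)
      pos <- c(pos, p)
    }
    signal_track(rep("chr1", length(pos)), rep("+", length(pos)), pos,
                 rep(1, length(pos)))
  }
  tracks <- list(n1 = mk_lib("NHS"), n2 = mk_lib("NHS"),
                 h1 = mk_lib("HS"), h2 = mk_lib("HS"))
  ref <- pool_tracks(tracks[1:2])
  cond <- c("NHS", "NHS", "HS", "HS")
  res <- pausing_change_test(ref, tracks, genes, rep(1, 4), cond)
  sig <- res$padj <= 0.001 & res$log2fc < 0
  expect_gte(mean(sig[lost]), 0.8)
  expect_lte(sum(sig[-lost]), 5)
  # relabeling the contrast direction negates every lfc, p unchanged
  swapped <- pausing_change_test(ref, tracks, genes, rep(1, 4), cond,
                                 reference = "HS")
  expect_equal(swapped$log2fc, -res$log2fc)
  expect_equal(swapped$p, res$p)
})
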