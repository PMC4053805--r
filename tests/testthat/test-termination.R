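test_that("gene bodies get 100 bins and flanks 200 bp bins, strand-oriented", {
  gs <- toy_gene_set(data.frame(gene_id = c("p", "m"), chrom = "chr1",
                                start = c(200001, 400001),
                                end = c(210000, 410000),
                                strand = c("+", "-")),
                     chrom_sizes = c(chr1 = 1e6))
  rs <- make_reads("s", "chr1", c(210051, 399801), c("+", "-"))
  bp <- bin_gene_and_flanks(gs, "p", rs)
  expect_equal(bp$body$n_bins, 100)
  expect_equal(bp$body$bin_size, 100)       # 10 kb gene
  expect_equal(length(bp$downstream$density), 500)
  expect_equal(bp$downstream$bin_size, 200)
  # the plus-strand read 50 bases past the PAS lands in downstream bin 1
  expect_gt(bp$downstream$density[1], 0)
  expect_equal(sum(bp$downstream$density > 0), 1)
  bm <- bin_gene_and_flanks(gs, "m", rs)
  # minus strand: downstream bin 1 abuts the PAS at the left gene edge
  expect_gt(bm$downstream$density[1], 0)
  expect_equal(sum(bm$downstream$density > 0), 1)
})

test_that("flanks truncate at chromosome ends and short genes are skipped", {
  gs <- toy_gene_set(data.frame(gene_id = "edge", chrom = "chr1",
                                start = 5001, end = 15000, strand = "-"),
                     chrom_sizes = c(chr1 = 5e5))
  rs <- make_reads("s", "chr1", integer(), "-")
  b <- bin_gene_and_flanks(gs, "edge", rs)
  expect_equal(length(b$downstream$density), 25)  # 5000 bases / 200
  tiny <- toy_gene_set(data.frame(gene_id = "t", chrom = "chr1",
                                  start = 1000, end = 1050, strand = "+"),
                       chrom_sizes = c(chr1 = 5e5))
  expect_warning(r <- bin_gene_and_flanks(tiny, "t", rs), "skipped")
  expect_null(r)
})

test_that("enrichment regions are maximal runs of window-qualified bins", {
  expect_equal(nrow(find_enrichment_regions(rep(0, 50))), 0)
  d <- rep(0, 60); d[21:40] <- 0.01
  r <- find_enrichment_regions(d)
  expect_equal(nrow(r), 1)
  expect_lte(r$start_bin, 21)
  expect_gte(r$end_bin, 40)
  expect_false(r$low_support)
  # an isolated hot bin qualifies via its covering windows but is flagged
  d2 <- rep(0, 60); d2[30] <- 0.06
  r2 <- find_enrichment_regions(d2)
  expect_equal(nrow(r2), 1)
  expect_true(r2$low_support)
  expect_true(r2$start_bin <= 30 && r2$end_bin >= 30)
})

test_that("enrichment regions match the brute-force oracle on random vectors", {
  set.seed(41)
  for (rep in 1:300) {
    n <- sample(5:80, 1)
    d <- ifelse(runif(n) < 0.3, runif(n, 0, 0.02), 0)
    r <- find_enrichment_regions(d)
    expect_equal(regions_to_qual(r, n), oracle_enrichment(d),
                 info = paste("case", rep))
  }
})

test_that("region fold changes floor counts at 1 per sample pair", {
  design <- default_design()
  cnt <- c(scr_1 = 2, scr_2 = 2, a5_1 = 6, a5_2 = 6, a3_1 = 6, a3_2 = 6)
  fc <- region_log2fc(cnt, design)
  expect_equal(unname(fc), rep(log2(3), 2))
  zero <- region_log2fc(setNames(rep(0, 6), design$sample_id), design)
  expect_equal(unname(zero), c(0, 0))  # everything floored to 1
  down <- region_log2fc(c(scr_1 = 4, scr_2 = 4, a5_1 = 1, a5_2 = 1,
                          a3_1 = 1, a3_2 = 1), design)
  expect_equal(unname(down), rep(-2, 2))
  expect_error(region_log2fc(cnt[-1], design), "missing sample")
})

test_that("candidate calling applies size, fold-change, expression and chain rules", {
  gs <- toy_gene_set(data.frame(gene_id = c("up", "down"), chrom = "chr1",
                                start = c(100001, 150001),
                                end = c(104000, 154000), strand = "+"),
                     chrom_sizes = c(chr1 = 1e6))
  expressed <- c(up = TRUE, down = TRUE)
  tbl <- data.frame(gene_id = c("up", "down"),
                    size = c(5000, 5000),
                    fc_5p = c(2, 2), fc_3p = c(2, 2))
  r <- call_readthrough_candidates(gs, tbl, expressed)
  expect_true(all(r$is_potential))
  # "down" sits 50 kb downstream of potential "up" on the same strand
  expect_equal(r$is_candidate, c(TRUE, FALSE))

  small <- transform(tbl, size = c(800, 800))
  expect_false(any(call_readthrough_candidates(gs, small,
                                               expressed)$is_potential))
  mid <- transform(tbl, size = c(2000, 2000))
  rm <- call_readthrough_candidates(gs, mid, expressed)
  expect_true(all(rm$is_potential))
  expect_false(any(rm$is_candidate))  # above 1 kb but not above 3 kb
  silent <- call_readthrough_candidates(gs, tbl,
                                        c(up = FALSE, down = TRUE))
  expect_false(silent$is_candidate[1])
})

test_that("adding an upstream potential can only demote, never promote", {
  gs <- toy_gene_set(data.frame(gene_id = c("a", "b", "c"), chrom = "chr1",
                                start = c(100001, 150001, 500001),
                                end = c(104000, 154000, 504000),
                                strand = "+"),
                     chrom_sizes = c(chr1 = 1e6))
  expressed <- c(a = TRUE, b = TRUE, c = TRUE)
  base <- data.frame(gene_id = c("a", "b", "c"), size = c(0, 5000, 5000),
                     fc_5p = c(NA, 2, 2), fc_3p = c(NA, 2, 2))
  with_up <- transform(base, size = c(5000, 5000, 5000),
                       fc_5p = c(2, 2, 2), fc_3p = c(2, 2, 2))
  r0 <- call_readthrough_candidates(gs, base, expressed)
  r1 <- call_readthrough_candidates(gs, with_up, expressed)
  expect_true(all(r1$is_candidate <= r0$is_candidate |
                    r1$gene_id == "a"))
  expect_true(r0$is_candidate[r0$gene_id == "b"])
  expect_false(r1$is_candidate[r1$gene_id == "b"])
  expect_true(r1$is_candidate[r1$gene_id == "c"])  # beyond 100 kb lookback
})

test_that("the require-both switch tightens the fold-change clause", {
  gs <- toy_gene_set(data.frame(gene_id = "g", chrom = "chr1",
                                start = 100001, end = 104000,
                                strand = "+"))
  tbl <- data.frame(gene_id = "g", size = 5000, fc_5p = 2, fc_3p = 0.1)
  expect_true(call_readthrough_candidates(gs, tbl,
                                          c(g = TRUE))$is_potential)
  expect_false(call_readthrough_candidates(gs, tbl, c(g = TRUE),
                                           require_both = TRUE)$is_potential)
})

test_that("noiseless step signals are segmented exactly", {
  x <- c(rep(0.05, 40), rep(0, 4960))
  est <- estimate_readthrough_extent(x)
  expect_equal(est$extent, 8000)
  expect_equal(estimate_readthrough_extent(rep(0, 5000))$extent, 0)
  # merge stops at a sub-threshold segment even if signal resumes
  y <- c(rep(0.05, 20), rep(0.002, 10), rep(0.05, 20), rep(0, 4950))
  expect_equal(estimate_readthrough_extent(y)$extent, 4000)
})

test_that("segmentation tolerates replicate-level noise", {
  set.seed(42)
  truth_bins <- 100
  x <- c(rpois(truth_bins, 8), rpois(5000 - truth_bins, 0.1)) / 200
  est <- estimate_readthrough_extent(x)
  expect_lte(abs(est$extent - truth_bins * 200), 0.1 * truth_bins * 200)
})

test_that("heatmap ordering sorts by average fold change with id ties", {
  tbl <- data.frame(gene_id = c("b", "a", "c"),
                    fc_5p = c(3.0, 1.6, 3.0), fc_3p = c(3.0, 1.6, 3.0))
  m <- matrix(0, 3, 4, dimnames = list(c("a", "b", "c"), NULL))
  o <- order_genes_for_heatmap(tbl, m)
  expect_equal(o$gene_id, c("b", "c", "a"))
  expect_equal(rownames(o$matrix), c("b", "c", "a"))
  single <- order_genes_for_heatmap(tbl[1, ])
  expect_equal(single$gene_id, "b")
})
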