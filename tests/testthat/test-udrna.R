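udrna_scene <- function(mirror = FALSE) {
  # one eligible plus-strand gene; optionally the strand-flipped,
  # coordinate-reflected version about position 400000
  if (!mirror) {
    toy_gene_set(data.frame(gene_id = "g", chrom = "chr1",
                            start = 100001, end = 104000, strand = "+"),
                 chrom_sizes = c(chr1 = 4e5))
  } else {
    toy_gene_set(data.frame(gene_id = "g", chrom = "chr1",
                            start = 4e5 - 104000, end = 4e5 - 100001,
                            strand = "-"),
                 chrom_sizes = c(chr1 = 4e5))
  }
}

scene_reads <- function(n_upstream_anti, mirror = FALSE, sample_id = "s",
                        strand_override = NULL) {
  # reads placed mid-window upstream of the TSS on the antisense strand
  if (!mirror) {
    starts <- seq(96001, by = 60, length.out = n_upstream_anti)
    st <- strand_override %||% "-"
  } else {
    starts <- 4e5 - (seq(96001, by = 60, length.out = n_upstream_anti) + 49)
    st <- strand_override %||% "+"
  }
  make_reads(sample_id, "chr1", starts, st)
}

unit_nf <- function(ids) {
  ct <- count_table(matrix(100, 1, length(ids),
                           dimnames = list("g", ids)))
  total_count_factors(ct)
}

test_that("divergent close pairs are excluded from the udRNA search", {
  lone <- toy_gene_set(data.frame(gene_id = "g", chrom = "chr1",
                                  start = 50001, end = 54000,
                                  strand = "+"))
  expect_equal(eligible_genes(lone), "g")
  div <- toy_gene_set(data.frame(gene_id = c("m", "p"), chrom = "chr1",
                                 start = c(20001, 32001),
                                 end = c(24000, 36000),
                                 strand = c("-", "+")))
  # TSS-to-TSS = 32001 - 24000 = 8001 < 10 kb, head-to-head
  expect_equal(eligible_genes(div), character())
  tandem <- toy_gene_set(data.frame(gene_id = c("a", "b"), chrom = "chr1",
                                    start = c(20001, 32001),
                                    end = c(24000, 36000), strand = "+"))
  expect_setequal(eligible_genes(tandem), c("a", "b"))
  # lincRNAs never enter the search
  linc <- toy_gene_set(data.frame(gene_id = "l", chrom = "chr1",
                                  start = 50001, end = 54000, strand = "+",
                                  biotype = "lincRNA"))
  expect_equal(eligible_genes(linc), character())
})

test_that("the udRNA threshold floors at 10 and doubles the densest window", {
  expect_equal(udrna_threshold(list(a = rep(0, 5), b = rep(2000, 5))), 10)
  expect_equal(udrna_threshold(list(a = 0.002 * 2000, b = 2000)), 20)
  expect_equal(udrna_threshold(list(a = 0.0008 * 2000, b = 2000)), 10)
  expect_equal(udrna_threshold(list(a = numeric(), b = numeric())), 10)
  set.seed(31)
  for (rep in 1:200) {
    k <- sample(1:5, 1)
    bg <- list(a = runif(k, 0, 30), b = sample(1000:2000, k, TRUE))
    expect_gte(udrna_threshold(bg), 10)
    expect_equal(udrna_threshold(bg),
                 max(10, 2 * 5000 * max(bg$a / bg$b)))
  }
})

test_that("udRNA detection needs enough antisense reads on the right strand", {
  gs <- udrna_scene()
  nf <- unit_nf(c("c1", "c2", "k1", "k2"))
  run <- function(n, strand_override = NULL) {
    ctrl <- list(scene_reads(0, sample_id = "c1"),
                 scene_reads(0, sample_id = "c2"))
    kd <- list(scene_reads(n, sample_id = "k1",
                           strand_override = strand_override),
               scene_reads(0, sample_id = "k2"))
    detect_udrnas(gs, ctrl, kd, nf)
  }
  expect_equal(run(15)$gene_id, "g")       # 15 >= 10, zero background
  expect_equal(nrow(run(9)), 0)            # below the floor
  expect_equal(nrow(run(15, strand_override = "+")), 0)  # wrong strand
  call <- run(15)
  expect_gte(call$threshold_used, 10)
  expect_match(call$detected_in, "k1")
})

test_that("detection requires balanced control and knockdown samples", {
  gs <- udrna_scene()
  nf <- unit_nf(c("c1", "k1", "k2"))
  ctrl <- list(scene_reads(0, sample_id = "c1"))
  kd <- list(scene_reads(15, sample_id = "k1"),
             scene_reads(0, sample_id = "k2"))
  expect_error(detect_udrnas(gs, ctrl, kd, nf), "equal number")
  expect_warning(detect_udrnas(gs, ctrl, kd, nf, allow_unbalanced = TRUE),
                 "unbalanced")
})

test_that("detection is symmetric under strand flip plus reflection", {
  for (mirror in c(FALSE, TRUE)) {
    gs <- udrna_scene(mirror)
    nf <- unit_nf(c("c1", "c2", "k1", "k2"))
    ctrl <- list(scene_reads(0, mirror, "c1"), scene_reads(0, mirror, "c2"))
    kd <- list(scene_reads(15, mirror, "k1"), scene_reads(0, mirror, "k2"))
    calls <- detect_udrnas(gs, ctrl, kd, nf)
    expect_equal(calls$gene_id, "g")
    expect_equal(calls$strand, if (mirror) "+" else "-")
  }
})

test_that("a readthrough sweep across the promoter is rejected by the background rule", {
  gs <- udrna_scene()
  nf <- unit_nf(c("c1", "c2", "k1", "k2"))
  # antisense reads covering the upstream window AND the region downstream
  # of the TSS at equal density: the two-fold criterion cannot be met
  sweep_reads <- function(id) make_reads(
    id, "chr1", seq(93001, 112000, by = 50), "-")
  ctrl <- list(scene_reads(0, sample_id = "c1"),
               scene_reads(0, sample_id = "c2"))
  kd <- list(sweep_reads("k1"), scene_reads(0, sample_id = "k2"))
  expect_equal(nrow(detect_udrnas(gs, ctrl, kd, nf)), 0)
})

test_that("udRNA responses are quantified with pseudocounted fold changes", {
  gs <- udrna_scene()
  nf <- unit_nf(c("c1", "c2", "k1", "k2"))
  ctrl <- list(scene_reads(9, sample_id = "c1"),
               scene_reads(9, sample_id = "c2"))
  kd <- list(scene_reads(30, sample_id = "k1"),
             scene_reads(30, sample_id = "k2"))
  calls <- detect_udrnas(gs, ctrl, kd, nf)
  out <- quantify_udrna_response(calls, kd, ctrl, nf)
  expect_equal(out$log2fc, log2(31 / 10), tolerance = 1e-12)
  expect_true(out$regulated)       # 3.1 > 2
  eq <- quantify_udrna_response(calls, ctrl, ctrl, nf)
  expect_equal(eq$log2fc, 0)
  expect_false(eq$regulated)
  mid <- quantify_udrna_response(calls,
                                 list(scene_reads(15, sample_id = "k1"),
                                      scene_reads(15, sample_id = "k2")),
                                 list(scene_reads(8, sample_id = "c1"),
                                      scene_reads(8, sample_id = "c2")), nf)
  expect_false(mid$regulated)      # 16/9 < 2: detected but not repressed
})
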