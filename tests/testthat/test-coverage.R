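test_that("BED6 reads round-trip through write and load", {
  rs <- make_reads("s1", "chr1", c(100, 300, 500, 700, 900),
                   c("+", "+", "+", "-", "-"))
  f <- tempfile(fileext = ".bed")
  write_reads_bed(rs, f)
  back <- load_reads(f, "s1")
  expect_equal(length(back$reads), 5)
  expect_equal(sum(strand(back$reads) == "+"), 3)
  expect_equal(sum(strand(back$reads) == "-"), 2)
  expect_equal(start(back$reads), start(rs$reads))
})

test_that("empty BED yields an empty read set", {
  f <- tempfile(fileext = ".bed")
  file.create(f)
  rs <- load_reads(f, "s1")
  expect_equal(length(rs$reads), 0)
})

test_that("BAM loading drops multi-mapped reads and keeps strand", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:chr1\tLN:10000",
               "r1\t0\tchr1\t100\t60\t50M\t*\t0\t0\t*\t*\tNH:i:1",
               "r2\t16\tchr1\t200\t60\t50M\t*\t0\t0\t*\t*\tNH:i:1",
               "r3\t0\tchr1\t300\t60\t50M\t*\t0\t0\t*\t*\tNH:i:2"), sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE)
  rs <- load_reads(bam, "s1")
  expect_equal(length(rs$reads), 2)  # NH=2 record excluded
  expect_equal(as.character(strand(rs$reads)), c("+", "-"))
})

test_that("reverse strandedness flips strands on load", {
  rs <- make_reads("s1", "chr1", c(100, 300), c("+", "-"))
  f <- tempfile(fileext = ".bed")
  write_reads_bed(rs, f)
  back <- load_reads(f, "s1", reverse_strandedness = TRUE)
  expect_equal(as.character(strand(back$reads)), c("-", "+"))
})

test_that("gene counting applies the half-overlap exon rule", {
  gs <- toy_gene_set(data.frame(gene_id = "gA", chrom = "chr1",
                                start = 1001, end = 2000, strand = "+",
                                exons = I(list(cbind(c(1, 501),
                                               c(200, 700))))))
  # read fully inside an exon; 25/50 exonic (counted, >= half);
  # 24/50 exonic (not counted); read on the wrong strand
  rs <- make_reads("s1", "chr1",
                   c(1051, 1200 - 24, 1200 - 23, 1051),
                   c("+", "+", "+", "-"))
  expect_equal(unname(count_gene_reads(rs, gs)), 2)
})

test_that("gene counting is invariant to splitting an exon into adjacent pieces", {
  whole <- toy_gene_set(data.frame(gene_id = "gA", chrom = "chr1",
                                   start = 1001, end = 2000, strand = "+",
                                   exons = I(list(cbind(1, 600)))))
  split3 <- toy_gene_set(data.frame(gene_id = "gA", chrom = "chr1",
                                    start = 1001, end = 2000, strand = "+",
                                    exons = I(list(cbind(c(1, 201, 401),
                                                   c(200, 400, 600))))))
  set.seed(3)
  rs <- make_reads("s1", "chr1", sample(900:2100, 200, TRUE),
                   sample(c("+", "-"), 200, TRUE))
  expect_equal(count_gene_reads(rs, whole), count_gene_reads(rs, split3))
})

test_that("RPKM follows its definition and homogeneity", {
  expect_equal(compute_rpkm(10, 500, 1e6), 20)
  expect_equal(compute_rpkm(0, 500, 1e6), 0)
  r1 <- compute_rpkm(c(10, 30), c(500, 1500), 1e6)
  r2 <- compute_rpkm(c(20, 60), c(500, 1500), 2e6)
  expect_equal(r1[1] / r1[2], r2[1] / r2[2])  # scale-free ratios
  expect_error(compute_rpkm(10, 0, 1e6), "positive")
  expect_error(compute_rpkm(10, 500, 0), "positive")
})

test_that("the expressed-gene rule uses a strict mean threshold", {
  expect_true(is_expressed(c(6, 7)))
  expect_false(is_expressed(c(5, 5)))
  expect_false(is_expressed(0))
  expect_error(is_expressed(numeric()), "control")
})

test_that("binned densities apportion reads fractionally", {
  iv <- GRanges("chr1", IRanges(1001, 1400))
  expect_equal(bin_density(make_reads("s", "chr1", integer(), "+"),
                           iv, "+", bin_size = 200)$density, c(0, 0))
  # one 200 nt read exactly filling one 200 bp bin -> density 1/200
  rs <- make_reads("s", "chr1", 1001, "+", len = 200)
  expect_equal(bin_density(rs, iv, "+", bin_size = 200)$density,
               c(0.005, 0))
  # read straddling two bins equally -> half a read in each
  rs2 <- make_reads("s", "chr1", 1176, "+", len = 50)
  expect_equal(bin_density(rs2, iv, "+", bin_size = 200)$counts,
               c(0.5, 0.5))
  expect_error(bin_density(rs, GRanges("chr1", IRanges(10, 5)), "+",
                           n_bins = 2))
})

test_that("density times bin size conserves the regional read mass", {
  set.seed(11)
  iv <- GRanges("chr1", IRanges(5001, 9000))
  for (rep in 1:10) {
    rs <- make_reads("s", "chr1", sample(4800:9200, 300, TRUE), "+")
    for (nb in c(1, 7, 40)) {
      dv <- bin_density(rs, iv, "+", n_bins = nb, scale = 1.7)
      # clipped fractional mass computed directly
      s0 <- pmax(start(rs$reads), 5001); e0 <- pmin(end(rs$reads), 9000)
      frac <- sum(pmax(e0 - s0 + 1, 0) / width(rs$reads))
      expect_equal(sum(dv$density * dv$bin_size), 1.7 * frac,
                   tolerance = 1e-10)
    }
  }
})

test_that("bin_density with a single bin equals count over size", {
  rs <- make_reads("s", "chr1", seq(2000, 2900, by = 100), "+")
  iv <- GRanges("chr1", IRanges(2001, 3000))
  dv <- bin_density(rs, iv, "+", n_bins = 1)
  s0 <- pmax(start(rs$reads), 2001); e0 <- pmin(end(rs$reads), 3000)
  frac <- sum(pmax(e0 - s0 + 1, 0) / width(rs$reads))
  expect_equal(dv$density, frac / 1000)
})

test_that("windowed fold-change profiles use the pseudocount", {
  rs_kd <- make_reads("kd", "chr1", c(10010, 10020, 10030), "+")
  rs_ct <- make_reads("ct", "chr1", 10010, "+")
  prof <- windowed_log2fc_profile(list(rs_kd), list(rs_ct), anchor = 10001,
                                  chrom = "chr1", span = 500, window = 500,
                                  strand = "+")
  expect_equal(prof$log2fc, c(0, 1))  # empty window 0; (3+1)/(1+1) -> 1
  same <- windowed_log2fc_profile(list(rs_kd), list(rs_kd), anchor = 10001,
                                  chrom = "chr1", span = 500, window = 100,
                                  strand = "+")
  expect_true(all(same$log2fc == 0))
  expect_error(windowed_log2fc_profile(list(rs_kd), list(rs_ct), 1000,
                                       "chr1", span = 500, window = 300,
                                       strand = "+"), "divide")
})
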