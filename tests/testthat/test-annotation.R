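write_gtf_lines <- function(lines) {
  f <- tempfile(fileext = ".gtf")
  writeLines(lines, f)
  f
}

gtf_exon <- function(chrom, start, end, strand, gene, tx = paste0(gene, ".t1"),
                     biotype = "protein_coding") {
  sprintf('%s\tx\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
          chrom, start, end, strand, gene, tx, biotype)
}

test_that("gene models are built from GTF with merged exons and strand-aware ends", {
  f <- write_gtf_lines(c(
    gtf_exon("chr1", 101, 200, "+", "gA"),
    gtf_exon("chr1", 301, 400, "+", "gA"),
    gtf_exon("chr1", 1001, 2000, "-", "gB")))
  gs <- load_gene_models(f)
  expect_equal(n_genes(gs), 2)
  a <- gs$genes[gs$genes$gene_id == "gA"]
  expect_equal(a$exonic_length, 200)
  expect_equal(a$tss, 101)
  expect_equal(a$pas, 400)
  b <- gs$genes[gs$genes$gene_id == "gB"]
  expect_equal(b$tss, 2000)  # minus strand: 5' end is the right coordinate
  expect_equal(b$pas, 1001)
  expect_equal(b$exonic_length, 1000)
})

test_that("empty GTF yields an empty GeneSet", {
  f <- write_gtf_lines(character())
  expect_equal(n_genes(load_gene_models(f)), 0)
})

test_that("overlapping exons are merged in the exonic length", {
  f <- write_gtf_lines(c(
    gtf_exon("chr1", 101, 200, "+", "gA", tx = "t1"),
    gtf_exon("chr1", 151, 250, "+", "gA", tx = "t2")))
  gs <- load_gene_models(f)
  expect_equal(gs$genes$exonic_length, 150)
})

test_that("final TSS is the 3'-most transcript start across isoforms", {
  f <- write_gtf_lines(c(
    gtf_exon("chr1", 101, 500, "+", "gA", tx = "t1"),
    gtf_exon("chr1", 301, 500, "+", "gA", tx = "t2")))
  gs <- load_gene_models(f)
  expect_equal(gs$genes$tss, 101)
  expect_equal(gs$genes$final_tss, 301)
  expect_equal(gs$genes$pas, 500)
})

test_that("genes with exons on both strands are dropped with a warning", {
  f <- write_gtf_lines(c(
    gtf_exon("chr1", 101, 200, "+", "gA"),
    gtf_exon("chr1", 301, 400, "-", "gA", tx = "gA.t2"),
    gtf_exon("chr1", 1001, 1200, "+", "gB")))
  expect_warning(gs <- load_gene_models(f), "strand")
  expect_equal(gs$genes$gene_id, "gB")
})

test_that("unknown chromosomes are rejected when a size table is given", {
  f <- write_gtf_lines(gtf_exon("chrZ", 101, 200, "+", "gA"))
  expect_error(load_gene_models(f, genome_sizes = c(chr1 = 1e6)),
               "unknown chromosome")
})

test_that("exon masks report unmasked sizes", {
  gs <- toy_gene_set(data.frame(gene_id = "gA", chrom = "chr1",
                                start = 501, end = 700, strand = "+"))
  mask <- build_exon_mask(gs, "+")
  q <- GRanges("chr1", IRanges(1, 2000))
  expect_equal(masked_size(mask, q), 1800)
  empty_mask <- build_exon_mask(gs, "-")
  expect_equal(masked_size(empty_mask, q), 2000)
  expect_equal(masked_size(mask, GRanges("chr1", IRanges(501, 700))), 0)
})

test_that("masked size is additive over disjoint query intervals", {
  set.seed(1)
  for (rep in 1:20) {
    n_ex <- sample(1:6, 1)
    s <- sort(sample(seq(1, 5000, by = 10), n_ex))
    df <- data.frame(gene_id = paste0("g", seq_len(n_ex)), chrom = "chr1",
                     start = s, end = s + sample(50:200, n_ex, TRUE),
                     strand = "+")
    gs <- toy_gene_set(df)
    mask <- build_exon_mask(gs, "+")
    cut <- sample(2000:4000, 1)
    whole <- GRanges("chr1", IRanges(1, 6000))
    parts <- GRanges("chr1", IRanges(c(1, cut + 1), c(cut, 6000)))
    expect_equal(masked_size(mask, whole), sum(masked_size(mask, parts)))
  }
})

test_that("promoter regions are strand-aware and clamped", {
  gs <- toy_gene_set(data.frame(gene_id = c("gP", "gM"), chrom = "chr1",
                                start = c(10001, 5001),
                                end = c(12000, 10000),
                                strand = c("+", "-")),
                     chrom_sizes = c(chr1 = 1e6))
  pr <- promoter_region(gs)
  p <- pr[names(pr) == "gP"]
  expect_equal(width(p), 6000)
  expect_equal(end(p) - gs$genes$tss[gs$genes$gene_id == "gP"], 999)
  m <- pr[names(pr) == "gM"]
  expect_equal(width(m), 6000)
  # minus strand: upstream extends to higher coordinates
  expect_equal(end(m) - gs$genes$tss[gs$genes$gene_id == "gM"], 5000)

  near <- toy_gene_set(data.frame(gene_id = "gE", chrom = "chr1",
                                  start = 2001, end = 4000, strand = "+"),
                       chrom_sizes = c(chr1 = 1e6))
  pe <- promoter_region(near)
  expect_equal(start(pe), 1)   # truncated at the chromosome start
  expect_equal(end(pe), 3000)
})

test_that("upstream windows sit on the opposite strand and clamp at bounds", {
  gs <- toy_gene_set(data.frame(gene_id = c("gP", "gM"), chrom = "chr1",
                                start = c(20001, 50001),
                                end = c(25000, 55000),
                                strand = c("+", "-")),
                     chrom_sizes = c(chr1 = 1e6))
  w <- upstream_window(gs)
  wp <- w[names(w) == "gP"]
  expect_equal(width(wp), 5000)
  expect_equal(as.character(strand(wp)), "-")
  expect_equal(end(wp), 20000)  # ends immediately before the TSS
  wm <- w[names(w) == "gM"]
  expect_equal(as.character(strand(wm)), "+")
  expect_equal(start(wm), 55001)

  near <- toy_gene_set(data.frame(gene_id = "gE", chrom = "chr1",
                                  start = 1001, end = 3000, strand = "+"),
                       chrom_sizes = c(chr1 = 1e6))
  we <- upstream_window(near)
  expect_equal(width(we), 1000)  # truncated, never negative
})

test_that("derived windows obey strand mirror symmetry", {
  # reflect coordinates about a pivot and flip strands: windows must map to
  # their reflections
  pivot <- 100000
  set.seed(7)
  for (rep in 1:10) {
    s <- sample(20000:60000, 1); len <- sample(2000:8000, 1)
    gs_f <- toy_gene_set(data.frame(gene_id = "g", chrom = "chr1",
                                    start = s, end = s + len, strand = "+"))
    gs_r <- toy_gene_set(data.frame(gene_id = "g", chrom = "chr1",
                                    start = pivot - (s + len),
                                    end = pivot - s, strand = "-"))
    for (fun in list(function(g) promoter_region(g),
                     function(g) upstream_window(g))) {
      wf <- fun(gs_f); wr <- fun(gs_r)
      expect_equal(start(wr), pivot - end(wf))
      expect_equal(end(wr), pivot - start(wf))
    }
  }
})

test_that("the overlap universe keeps long protein-coding and lincRNA genes", {
  gs <- toy_gene_set(data.frame(
    gene_id = c("long_pc", "short_pc", "long_linc", "long_other"),
    chrom = "chr1", start = c(1000, 20000, 40000, 60000),
    end = c(3000, 20800, 42000, 62000), strand = "+",
    biotype = c("protein_coding", "protein_coding", "lincRNA", "other")))
  expect_setequal(overlap_universe(gs), c("long_pc", "long_linc"))
})
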