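# In-code fixtures shared across the suite.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# single-exon (or multi-exon) gene set built directly from a spec table:
# df columns gene_id, chrom, start, end, strand, optional biotype,
# optional exons (list of 2-col matrices relative to gene start, 1-based)
toy_gene_set <- function(df, chrom_sizes = NULL) {
  exl <- list()
  for (i in seq_len(nrow(df))) {
    ex <- if (is.null(df$exons)) NULL else df$exons[[i]]
    if (is.null(ex)) ex <- cbind(1, df$end[i] - df$start[i] + 1)
    exl[[df$gene_id[i]]] <- GRanges(df$chrom[i],
                                    IRanges(df$start[i] + ex[, 1] - 1,
                                            df$start[i] + ex[, 2] - 1),
                                    strand = df$strand[i])
  }
  g <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand)
  g$gene_id <- df$gene_id
  g$biotype <- df$biotype %||% rep("protein_coding", nrow(df))
  plus <- df$strand == "+"
  g$tss <- ifelse(plus, df$start, df$end)
  g$final_tss <- g$tss
  g$pas <- ifelse(plus, df$end, df$start)
  g$exonic_length <- vapply(exl[df$gene_id], function(x)
    sum(width(reduce(x))), numeric(1))
  gene_set(g, methods::as(exl, "GRangesList"), chrom_sizes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stranded reads from start positions
make_reads <- function(sample_id, chrom, starts, strand, len = 50,
                       total_mapped = NULL) {
  gr <- if (length(starts) == 0) GRanges() else
    GRanges(chrom, IRanges(starts, starts + len - 1), strand = strand)
  stranded_read_set(gr, sample_id, total_mapped %||% length(gr))
}

# small simulation config used by integration and determinism tests
small_sim_config <- function(seed = 5) {
  sim_config(seed = seed, chrom_length = 2.8e6,
             n_null = 4, n_null_silent = 1, n_null_lincrna = 1,
             n_direct = 3, n_udrna = 3, n_readthrough = 2,
             n_passenger = 1, n_confounder = 1, n_divergent_pairs = 1)
}

# brute-force sliding-window enrichment oracle (O(n * w))
oracle_enrichment <- function(density, min_density = 0.005, window = 10) {
  n <- length(density)
  if (n == 0) return(integer())
  w <- min(window, n)
  qual <- logical(n)
  for (i in seq_len(n - w + 1)) {
    if (mean(density[i:(i + w - 1)]) >= min_density)
      qual[i:(i + w - 1)] <- TRUE
  }
  qual
}

regions_to_qual <- function(regions, n) {
  qual <- logical(n)
  for (i in seq_len(nrow(regions)))
    qual[regions$start_bin[i]:regions$end_bin[i]] <- TRUE
  qual
}

# brute-force BH step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (k in m:1) {
    val <- min(prev, p[o[k]] * m / k)
    q[o[k]] <- val
    prev <- val
  }
  q
}

# two-sided Fisher p by hypergeometric enumeration
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  x <- lo:hi
  probs <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
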