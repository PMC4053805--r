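# Sorted per-(chromosome, strand) read coordinate pools.
#
# The detectors interrogate tens of thousands of small windows per sample;
# building interval trees per query is wasteful. A pool holds read starts
# and ends sorted by start, so window queries are binary searches.

read_pool <- function(rs) {
  gr <- rs$reads
  chrom <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  s <- GenomicRanges::start(gr)
  e <- GenomicRanges::end(gr)
  pool <- list()
  for (ch in unique(chrom)) {
    pool[[ch]] <- list()
    for (st in c("+", "-")) {
      idx <- which(chrom == ch & strand == st)
      if (length(idx)) {
        o <- idx[order(s[idx])]
        pool[[ch]][[st]] <- list(starts = s[o], ends = e[o],
                                 maxw = max(e[o] - s[o] + 1))
      } else {
        pool[[ch]][[st]] <- list(starts = integer(), ends = integer(),
                                 maxw = 1L)
      }
    }
  }
  structure(list(pool = pool, sample_id = rs$sample_id), class = "ReadPool")
}

# indices (within the chrom/strand slot) of reads overlapping [lo, hi]
pool_hits <- function(pp, chrom, strand, lo, hi) {
  slot <- pp$pool[[chrom]][[strand]]
  if (is.null(slot) || length(slot$starts) == 0) return(integer())
  i1 <- findInterval(lo - slot$maxw, slot$starts) + 1L
  i2 <- findInterval(hi, slot$starts)
  if (i2 < i1) return(integer())
  cand <- i1:i2
  cand[slot$ends[cand] >= lo]
}

pool_count <- function(pp, chrom, strand, lo, hi) {
  length(pool_hits(pp, chrom, strand, lo, hi))
}

# reads overlapping [lo, hi] as plain start/end vectors
pool_slice <- function(pp, chrom, strand, lo, hi) {
  slot <- pp$pool[[chrom]][[strand]]
  idx <- pool_hits(pp, chrom, strand, lo, hi)
  list(starts = slot$starts[idx], ends = slot$ends[idx])
}

# fractional-overlap binning kernel: reads (s, e) apportioned to n bins of
# continuous width w starting at 0-based origin S0; each read contributes
# overlap/length per bin
bin_frac_counts <- function(s, e, S0, w, n) {
  counts <- numeric(n)
  if (length(s) == 0) return(counts)
  s0 <- s - 1; e0 <- e
  len <- e0 - s0
  cs <- pmax(s0, S0); ce <- pmin(e0, S0 + n * w)
  keep <- ce > cs
  if (!any(keep)) return(counts)
  cs <- cs[keep]; ce <- ce[keep]; len <- len[keep]
  i1 <- floor((cs - S0) / w)
  K <- max(ceiling((ce - cs) / w)) + 1
  for (k in seq_len(K) - 1) {
    idx <- i1 + k
    ok <- idx < n
    if (!any(ok)) break
    lo <- S0 + idx * w; hi <- lo + w
    ov <- pmin(ce, hi) - pmax(cs, lo)
    ov[ov < 0] <- 0
    ok <- ok & ov > 0
    if (any(ok)) {
      inc <- rowsum(ov[ok] / len[ok], idx[ok])
      counts[as.integer(rownames(inc)) + 1] <-
        counts[as.integer(rownames(inc)) + 1] + inc[, 1]
    }
  }
  counts
}
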