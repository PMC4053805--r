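#' Local background estimation from exon-masked flanking windows
#'
#' Background transcription around a gene is estimated from five 2 kb
#' windows at 1-3, 3-5, 5-7, 7-9 and 9-11 kb from an anchor position,
#' with annotated exon bases on the counted strand masked out so the
#' estimate reflects intronic and intergenic transcription only. Windows
#' truncated at chromosome bounds keep their remaining bases; fully masked
#' or fully truncated windows are dropped.
#'
#' @name background
NULL

bg_offsets_default <- function() c(1, 3, 5, 7, 9) * 1000

new_background_estimate <- function(gene_id, sample_id, windows, a, b, side) {
  structure(list(gene_id = gene_id, sample_id = sample_id, windows = windows,
                 a = a, b = b, side = side),
            class = "BackgroundEstimate")
}

#' @export
print.BackgroundEstimate <- function(x, ...) {
  cat("BackgroundEstimate", x$side, "for", x$gene_id, "sample", x$sample_id,
      ":", length(x$a), "retained window(s)\n")
  invisible(x)
}

# five flanking windows walking away from `anchor` in `direction` (+1 right,
# -1 left); returns GRanges possibly with zero-width (dropped) entries.
flank_windows <- function(chrom, anchor, direction, chrom_sizes,
                          offsets = bg_offsets_default(), width = 2000) {
  if (direction > 0) {
    s <- anchor + offsets
    e <- s + width - 1
  } else {
    e <- anchor - offsets
    s <- e - width + 1
  }
  cl <- clamp_positions(s, e, rep(chrom, length(s)), chrom_sizes)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(cl$start, cl$end))
}

# sample-independent geometry of a gene's background windows: retained
# windows, their unmasked parts and unmasked sizes, and the counted strand
bg_geometry <- function(gs, gene_id, side, mask,
                        offsets = bg_offsets_default(), width = 2000) {
  g <- gs$genes[match(gene_id, gs$genes$gene_id)]
  strand <- as.character(GenomicRanges::strand(g))
  chrom <- as.character(GenomicRanges::seqnames(g))
  if (side == "upstream_sense") {
    anchor <- g$tss
    direction <- if (strand == "+") -1 else 1
    count_strand <- strand
  } else {
    anchor <- g$final_tss
    direction <- if (strand == "+") 1 else -1
    count_strand <- if (strand == "+") "-" else "+"
  }
  win <- flank_windows(chrom, anchor, direction, gs$chrom_sizes, offsets,
                       width)
  win <- win[GenomicRanges::width(win) > 0]
  parts <- lapply(seq_along(win), function(i)
    mask_complement(mask, chrom, GenomicRanges::start(win)[i],
                    GenomicRanges::end(win)[i]))
  b <- vapply(parts, function(p) sum(p[, "end"] - p[, "start"] + 1),
              numeric(1))
  keep <- b > 0
  win <- win[keep]; parts <- parts[keep]
  pt <- if (length(parts))
    data.frame(window = rep(seq_along(parts),
                            vapply(parts, nrow, integer(1))),
               start = unlist(lapply(parts, function(p) p[, "start"])),
               end = unlist(lapply(parts, function(p) p[, "end"])))
  else data.frame(window = integer(), start = numeric(), end = numeric())
  list(gene_id = gene_id, windows = win, b = b[keep], chrom = chrom,
       count_strand = count_strand, side = side, part_tbl = pt)
}

bg_count <- function(geom, rs, scale = 1) {
  pp <- if (inherits(rs, "ReadPool")) rs else read_pool(rs)
  n <- length(geom$windows)
  out <- numeric(n)
  pt <- geom$part_tbl
  for (wi in seq_len(n)) {
    rows <- which(pt$window == wi)
    idx <- unlist(lapply(rows, function(r)
      pool_hits(pp, geom$chrom, geom$count_strand, pt$start[r],
                pt$end[r])))
    out[wi] <- length(unique(idx))
  }
  out * scale
}

#' Upstream same-strand background estimate
#'
#' Five 2 kb windows at 1-11 kb upstream of the gene start (its 5'-most
#' TSS), strand-aware. Reads are counted on the gene's own strand; exons of
#' other genes on that strand are masked out.
#'
#' @param gs a `GeneSet`.
#' @param gene_id gene identifier.
#' @param rs a `StrandedReadSet`.
#' @param mask `ExonMask` for the gene's strand.
#' @param scale normalization multiplier for this sample (default 1).
#' @param offsets window offsets in bases from the anchor.
#' @param width window width in bases.
#' @return A `BackgroundEstimate` with per-window normalized counts `a` and
#'   unmasked sizes `b`.
#' @export
upstream_background <- function(gs, gene_id, rs, mask, scale = 1,
                                offsets = bg_offsets_default(),
                                width = 2000) {
  geom <- bg_geometry(gs, gene_id, "upstream_sense", mask, offsets, width)
  new_background_estimate(gene_id, rs$sample_id, geom$windows,
                          bg_count(geom, rs, scale), geom$b, geom$side)
}

#' Downstream antisense background estimate
#'
#' Five 2 kb windows at 1-11 kb downstream (3' direction) of the gene's
#' final TSS, with reads counted on the strand opposite to the gene and
#' opposite-strand exons masked out. This is the background against which
#' putative udRNA regions are required to be two-fold enriched, which
#' distinguishes genuine upstream divergent transcription from failed
#' termination of a downstream gene on the opposite strand sweeping across
#' the promoter.
#'
#' @inheritParams upstream_background
#' @param mask `ExonMask` for the strand opposite to the gene.
#' @return A `BackgroundEstimate`.
#' @export
downstream_antisense_background <- function(gs, gene_id, rs, mask,
                                            scale = 1,
                                            offsets = bg_offsets_default(),
                                            width = 2000) {
  geom <- bg_geometry(gs, gene_id, "downstream_antisense", mask, offsets,
                      width)
  new_background_estimate(gene_id, rs$sample_id, geom$windows,
                          bg_count(geom, rs, scale), geom$b, geom$side)
}

#' Background-adjusted read count
#'
#' Subtracts the scaled local background from a gene's (normalized) read
#' count: `max(0, g - l * median_j(a_j / b_j))`, where the median runs over
#' the retained background windows (even counts use the midpoint of the two
#' central values). Expression below background is set to zero. With no
#' retained windows the count is returned unchanged with a warning (no
#' evidence either way, so the adjustment is conservatively a no-op).
#'
#' @param g normalized gene read count.
#' @param l exonic length of the gene in bases (> 0).
#' @param bg a `BackgroundEstimate` (or list with elements `a`, `b`).
#' @return Adjusted count (>= 0, <= g).
#' @export
background_adjusted_count <- function(g, l, bg) {
  if (l <= 0) stop("exonic length must be positive")
  if (length(bg$a) == 0) {
    warning("no retained background window; returning count unchanged")
    return(g)
  }
  max(0, g - l * stats::median(bg$a / bg$b))
}

#' Background-adjusted count matrix for all genes
#'
#' Applies the background adjustment to every gene and sample, using
#' per-sample upstream same-strand background estimates on normalized
#' counts.
#'
#' @param gs a `GeneSet`.
#' @param ct a `CountTable` of gene counts (rows named by gene id).
#' @param read_sets named list of `StrandedReadSet`s (one per sample).
#' @param nf a `NormalizationFactors` object.
#' @return Matrix of background-adjusted normalized counts.
#' @export
adjusted_count_matrix <- function(gs, ct, read_sets, nf) {
  masks <- list("+" = build_exon_mask(gs, "+"),
                "-" = build_exon_mask(gs, "-"))
  norm <- normalized_counts(ct, nf)
  ids <- rownames(norm)
  out <- norm
  glen <- gs$genes$exonic_length[match(ids, gs$genes$gene_id)]
  gstr <- as.character(GenomicRanges::strand(gs$genes))[
    match(ids, gs$genes$gene_id)]
  geoms <- lapply(seq_along(ids), function(i)
    bg_geometry(gs, ids[i], "upstream_sense", masks[[gstr[i]]]))
  for (s in colnames(norm)) {
    pp <- read_pool(read_sets[[s]])
    sc <- norm_scale(nf, s)
    for (i in seq_along(ids)) {
      geom <- geoms[[i]]
      if (length(geom$b) == 0) next  # no evidence: adjustment is a no-op
      a <- bg_count(geom, pp, sc)
      out[i, s] <- max(0, norm[i, s] -
                         glen[i] * stats::median(a / geom$b))
    }
  }
  out
}
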