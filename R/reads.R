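#' Stranded read sets
#'
#' A `StrandedReadSet` holds uniquely mapped read alignments as a stranded
#' `GRanges` plus the per-sample total mapped read count used for
#' normalization.
#'
#' @param reads `GRanges` with strand `+`/`-` (aligned spans).
#' @param sample_id sample identifier.
#' @param total_mapped total mapped reads for the sample; defaults to the
#'   number of stored reads.
#' @return An object of class `StrandedReadSet`.
#' @export
stranded_read_set <- function(reads, sample_id, total_mapped = length(reads)) {
  stopifnot(methods::is(reads, "GRanges"))
  if (length(reads) && any(as.character(GenomicRanges::strand(reads)) == "*"))
    stop("reads must carry strand information")
  structure(list(reads = reads, sample_id = sample_id,
                 total_mapped = as.numeric(total_mapped)),
            class = "StrandedReadSet")
}

#' @export
print.StrandedReadSet <- function(x, ...) {
  cat("StrandedReadSet", x$sample_id, "with", length(x$reads), "reads (",
      x$total_mapped, "total mapped )\n")
  invisible(x)
}

#' Load uniquely mapped reads from BED6 or BAM
#'
#' BED6 input is read natively (0-based half-open converted on the fly by the
#' importer); BAM input drops unmapped, secondary, and multi-mapping records
#' (`NH` tag > 1). If the sequencing protocol yields reads antisense to the
#' transcript, set `reverse_strandedness = TRUE` to flip strands on load.
#'
#' @param path path to a `.bed` or `.bam` file.
#' @param sample_id sample identifier.
#' @param reverse_strandedness flip read strands on load (dUTP-style
#'   protocols). Default `FALSE` (ligation protocols preserve sense).
#' @param known_chroms optional character vector; reads on other chromosomes
#'   are skipped with a warning.
#' @return A `StrandedReadSet`.
#' @export
load_reads <- function(path, sample_id, reverse_strandedness = FALSE,
                       known_chroms = NULL) {
  if (!file.exists(path)) stop("read file not found: ", path)
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    ga <- GenomicAlignments::readGAlignments(
      path, param = Rsamtools::ScanBamParam(
        tag = "NH",
        flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                      isSecondaryAlignment = FALSE)))
    nh <- S4Vectors::mcols(ga)$NH
    keep <- is.na(nh) | nh <= 1L
    gr <- GenomicRanges::granges(ga[keep])
  } else {
    gr <- rtracklayer::import(path, format = "BED")
    gr <- GenomicRanges::granges(gr)
  }
  if (length(gr) && any(as.character(GenomicRanges::strand(gr)) == "*"))
    stop("input reads lack strand information: ", path)
  if (!is.null(known_chroms)) {
    chr <- as.character(GenomicRanges::seqnames(gr))
    bad <- !(chr %in% known_chroms)
    if (any(bad)) {
      warning("skipping ", sum(bad), " reads on unknown chromosome(s): ",
              paste(unique(chr[bad]), collapse = ", "))
      gr <- gr[!bad]
    }
  }
  if (reverse_strandedness) {
    s <- as.character(GenomicRanges::strand(gr))
    GenomicRanges::strand(gr) <- ifelse(s == "+", "-", "+")
  }
  stranded_read_set(gr, sample_id, total_mapped = length(gr))
}

reads_on_strand <- function(rs, strand) {
  rs$reads[as.character(GenomicRanges::strand(rs$reads)) == strand]
}

# align seqlevels of two GRanges so overlap machinery never warns about
# disjoint Seqinfo objects
align_seqlevels <- function(a, b) {
  u <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- u
  GenomeInfoDb::seqlevels(b) <- u
  list(a = a, b = b)
}

#' Count reads in regions (at least one overlapping base)
#'
#' @param rs a `StrandedReadSet`.
#' @param regions `GRanges`; only reads on `strand` are counted.
#' @param strand strand to count on; `NULL` uses each region's own strand.
#' @return Numeric vector of counts, one per region.
#' @export
count_region_reads <- function(rs, regions, strand = NULL) {
  if (length(regions) == 0) return(numeric())
  if (is.null(strand)) {
    out <- numeric(length(regions))
    for (s in c("+", "-")) {
      idx <- as.character(GenomicRanges::strand(regions)) == s
      if (any(idx)) {
        al <- align_seqlevels(regions[idx], reads_on_strand(rs, s))
        out[idx] <- GenomicRanges::countOverlaps(al$a, al$b,
                                                 ignore.strand = TRUE)
      }
    }
    return(out)
  }
  al <- align_seqlevels(regions, reads_on_strand(rs, strand))
  GenomicRanges::countOverlaps(al$a, al$b, ignore.strand = TRUE)
}

# reads overlapping any unmasked part of each window (unique read-window pairs)
count_reads_in_parts <- function(reads, parts, n_windows) {
  out <- numeric(n_windows)
  if (length(parts) == 0 || length(reads) == 0) return(out)
  hits <- GenomicRanges::findOverlaps(parts, reads, ignore.strand = TRUE)
  if (length(hits) == 0) return(out)
  key <- paste(parts$window[S4Vectors::queryHits(hits)],
               S4Vectors::subjectHits(hits))
  uq <- !duplicated(key)
  tab <- table(parts$window[S4Vectors::queryHits(hits)][uq])
  out[as.integer(names(tab))] <- as.numeric(tab)
  out
}

#' Exon-overlap gene read counting
#'
#' Counts reads on the gene's strand whose overlap with the merged exons is
#' at least half the read's aligned length. This retains exonic reads where
#' partial exons are annotated or reads align suboptimally at exon
#' boundaries.
#'
#' @param rs a `StrandedReadSet`.
#' @param gs a `GeneSet`.
#' @param gene_ids optional subset of gene ids.
#' @param min_overlap_frac minimum exonic fraction of the aligned length
#'   (default 0.5).
#' @return Named numeric vector of counts per gene.
#' @export
count_gene_reads <- function(rs, gs, gene_ids = NULL,
                             min_overlap_frac = 0.5) {
  g <- gs$genes
  if (!is.null(gene_ids)) g <- g[match(gene_ids, g$gene_id)]
  ids <- g$gene_id
  out <- stats::setNames(numeric(length(ids)), ids)
  ex <- unlist(gs$exons[ids], use.names = TRUE)
  if (length(ex) == 0 || length(rs$reads) == 0) return(out)
  gene_of <- names(ex)  # GRangesList unlist repeats element names per range
  for (s in c("+", "-")) {
    exs <- ex[as.character(GenomicRanges::strand(ex)) == s]
    if (length(exs) == 0) next
    gos <- gene_of[as.character(GenomicRanges::strand(ex)) == s]
    reads <- reads_on_strand(rs, s)
    if (length(reads) == 0) next
    al <- align_seqlevels(reads, exs)
    reads <- al$a; exs <- al$b
    hits <- GenomicRanges::findOverlaps(reads, exs, ignore.strand = TRUE)
    if (length(hits) == 0) next
    ovw <- GenomicRanges::width(GenomicRanges::pintersect(
      reads[S4Vectors::queryHits(hits)], exs[S4Vectors::subjectHits(hits)],
      ignore.strand = TRUE))
    key <- paste(S4Vectors::queryHits(hits), gos[S4Vectors::subjectHits(hits)],
                 sep = "\r")
    tot <- tapply(ovw, key, sum)  # exons are merged, so no double counting
    ridx <- as.integer(sub("\r.*$", "", names(tot)))
    gidx <- sub("^[0-9]+\r", "", names(tot))
    pass <- tot >= min_overlap_frac * GenomicRanges::width(reads)[ridx]
    if (any(pass)) {
      tab <- table(gidx[pass])
      out[names(tab)] <- out[names(tab)] + as.numeric(tab)
    }
  }
  out
}

#' Reads per kilobase of exon model per million mapped reads
#'
#' @param count read count(s).
#' @param exonic_length exonic length in bases (> 0).
#' @param total_gene_mapped total reads mapped to genes in the sample (> 0).
#' @return RPKM value(s).
#' @export
compute_rpkm <- function(count, exonic_length, total_gene_mapped) {
  if (any(exonic_length <= 0)) stop("exonic_length must be positive")
  if (any(total_gene_mapped <= 0)) stop("total_gene_mapped must be positive")
  count / (exonic_length / 1000) / (total_gene_mapped / 1e6)
}

#' Expressed-gene rule
#'
#' A gene is expressed if the mean of its control-sample RPKMs exceeds the
#' threshold (strictly).
#'
#' @param control_rpkms numeric vector (or matrix genes x samples) of control
#'   RPKMs.
#' @param threshold RPKM threshold (default 5).
#' @return Logical flag (or vector for a matrix input).
#' @export
is_expressed <- function(control_rpkms, threshold = 5) {
  if (is.matrix(control_rpkms)) {
    if (ncol(control_rpkms) < 1) stop("at least one control sample required")
    return(rowMeans(control_rpkms) > threshold)
  }
  if (length(control_rpkms) == 0) stop("at least one control sample required")
  mean(control_rpkms) > threshold
}

#' Binned normalized read density
#'
#' Tiles an interval into bins and assigns each read fractionally by the
#' overlap of its aligned span, so that summing density x bin size over the
#' interval returns the region's (fractional) normalized read count.
#'
#' @param rs a `StrandedReadSet`.
#' @param interval single `GRanges` interval.
#' @param strand strand to count on.
#' @param n_bins number of equal bins (alternative to `bin_size`).
#' @param bin_size bin size in bases (alternative to `n_bins`).
#' @param scale per-sample normalization multiplier applied to counts
#'   (default 1).
#' @return List of class `DensityVector` with elements `density` (reads per
#'   base per bin), `counts` (normalized fractional counts per bin),
#'   `bin_size`, `n_bins`, `interval`, `strand`.
#' @export
bin_density <- function(rs, interval, strand, n_bins = NULL, bin_size = NULL,
                        scale = 1) {
  stopifnot(length(interval) == 1)
  W <- GenomicRanges::width(interval)
  if (W <= 0) stop("zero-size interval")
  if (is.null(n_bins)) {
    if (is.null(bin_size)) stop("give n_bins or bin_size")
    n_bins <- ceiling(W / bin_size)
    w <- bin_size
  } else {
    if (W < n_bins) stop("interval smaller than number of bins")
    w <- W / n_bins
  }
  S0 <- GenomicRanges::start(interval) - 1  # continuous 0-based origin
  if (inherits(rs, "ReadPool")) {
    sl <- pool_slice(rs, as.character(GenomicRanges::seqnames(interval)),
                     strand, GenomicRanges::start(interval),
                     GenomicRanges::end(interval))
  } else {
    reads <- reads_on_strand(rs, strand)
    reads <- IRanges::subsetByOverlaps(reads, interval,
                                       ignore.strand = TRUE)
    sl <- list(starts = GenomicRanges::start(reads),
               ends = GenomicRanges::end(reads))
  }
  counts <- bin_frac_counts(sl$starts, sl$ends, S0, w, n_bins) * scale
  structure(list(density = counts / w, counts = counts, bin_size = w,
                 n_bins = n_bins, interval = interval, strand = strand),
            class = "DensityVector")
}

#' Windowed log2 fold-change profile
#'
#' Log2 ratio of mean normalized knockdown to control counts (pseudocount 1)
#' in fixed windows tiling `[anchor - span, anchor + span)`. Windows are
#' reported 5' to 3' relative to `strand`.
#'
#' @param kd list of knockdown `StrandedReadSet`s.
#' @param ctrl list of control `StrandedReadSet`s.
#' @param anchor anchor position (e.g. a TSS).
#' @param chrom chromosome of the anchor.
#' @param span half-width of the profiled region in bases.
#' @param window window size in bases; must divide `span`.
#' @param strand strand profiled.
#' @param kd_scales,ctrl_scales per-sample normalization multipliers.
#' @param pseudocount pseudocount added to mean normalized counts (default 1).
#' @return data.frame with `offset` (window start relative to anchor,
#'   strand-oriented) and `log2fc`.
#' @export
windowed_log2fc_profile <- function(kd, ctrl, anchor, chrom, span, window,
                                    strand,
                                    kd_scales = rep(1, length(kd)),
                                    ctrl_scales = rep(1, length(ctrl)),
                                    pseudocount = 1) {
  if (span %% window != 0) stop("window must divide span")
  if (!length(kd) || !length(ctrl)) stop("both groups must be non-empty")
  iv <- GenomicRanges::GRanges(chrom, IRanges::IRanges(anchor - span,
                                                       anchor + span - 1))
  n <- 2 * span / window
  grp <- function(sets, scales) {
    m <- sapply(seq_along(sets), function(i)
      bin_density(sets[[i]], iv, strand, bin_size = window,
                  scale = scales[i])$counts[seq_len(n)])
    rowMeans(as.matrix(m))
  }
  fc <- log2((grp(kd, kd_scales) + pseudocount) /
               (grp(ctrl, ctrl_scales) + pseudocount))
  off <- seq(-span, span - window, by = window)
  if (strand == "-") fc <- rev(fc)
  data.frame(offset = off, log2fc = fc)
}
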