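#' Gene models and derived genomic windows
#'
#' A `GeneSet` bundles per-gene models (interval, merged exons, TSS, final
#' TSS, polyadenylation site, exonic length) with the chromosome size table.
#' All coordinates are 1-based closed intervals (the native R/Bioconductor
#' convention); GTF input is used as-is and BED input/output is converted at
#' the boundary.
#'
#' @param genes `GRanges` of gene intervals with metadata columns `gene_id`,
#'   `biotype`, `tss`, `final_tss`, `pas`, `exonic_length`.
#' @param exons named `GRangesList` of merged exons, one element per gene.
#' @param chrom_sizes optional named numeric vector of chromosome lengths.
#' @return An object of class `GeneSet`.
#' @export
gene_set <- function(genes, exons, chrom_sizes = NULL) {
  stopifnot(methods::is(genes, "GRanges"))
  ids <- genes$gene_id
  if (length(ids) == 0)
    return(structure(list(genes = genes,
                          exons = GenomicRanges::GRangesList(),
                          chrom_sizes = chrom_sizes), class = "GeneSet"))
  if (anyDuplicated(ids)) stop("duplicate gene_id in GeneSet")
  if (!all(ids %in% names(exons))) stop("exons missing for some genes")
  exons <- exons[ids]
  # one shared Seqinfo across all elements (genes may sit on different
  # chromosomes)
  exons <- suppressWarnings(
    GenomicRanges::GRangesList(as.list(exons), compress = TRUE))
  u <- union(GenomeInfoDb::seqlevels(genes), GenomeInfoDb::seqlevels(exons))
  GenomeInfoDb::seqlevels(genes) <- u
  GenomeInfoDb::seqlevels(exons) <- u
  # genes sorted by (chrom, start) for neighbour queries
  ord <- order(as.character(GenomicRanges::seqnames(genes)),
               GenomicRanges::start(genes))
  genes <- genes[ord]
  exons <- exons[genes$gene_id]
  if (!is.null(chrom_sizes)) {
    bad <- setdiff(as.character(unique(GenomicRanges::seqnames(genes))),
                   names(chrom_sizes))
    if (length(bad)) stop("genes on chromosomes absent from size table: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(genes = genes, exons = exons, chrom_sizes = chrom_sizes),
            class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat("GeneSet with", length(x$genes), "genes on",
      length(unique(as.character(GenomicRanges::seqnames(x$genes)))),
      "chromosome(s)\n")
  invisible(x)
}

#' Number of genes in a GeneSet
#' @param gs a `GeneSet`.
#' @export
n_genes <- function(gs) length(gs$genes)

biotype_class <- function(x) {
  out <- rep("other", length(x))
  out[x %in% "protein_coding"] <- "protein_coding"
  out[x %in% c("lincRNA", "lincrna", "lncRNA")] <- "lincRNA"
  out
}

#' Load gene models from a GTF annotation
#'
#' Builds one gene model per `gene_id` from the exon features of a GTF file
#' (Ensembl attribute dialect: `gene_id`, `transcript_id`, `gene_biotype`).
#' Exons are merged per gene; the TSS is the 5'-most transcript start across
#' isoforms, the final TSS the 3'-most transcript start, and the PAS the
#' 3'-most transcript end, all respecting strand. Genes whose exons span
#' multiple chromosomes or strands are dropped with a warning, since every
#' downstream detection assumes a single stranded locus.
#'
#' @param annotation_path path to a GTF file with exon features.
#' @param genome_sizes optional named numeric vector (or two-column
#'   chrom/length data frame) of chromosome lengths.
#' @return A `GeneSet`.
#' @export
load_gene_models <- function(annotation_path, genome_sizes = NULL) {
  if (!file.exists(annotation_path)) stop("annotation file not found: ",
                                          annotation_path)
  if (is.data.frame(genome_sizes)) {
    genome_sizes <- stats::setNames(as.numeric(genome_sizes[[2]]),
                                    as.character(genome_sizes[[1]]))
  }
  first <- readLines(annotation_path, n = 100)
  if (!any(nzchar(first) & !startsWith(first, "#"))) {
    gtf <- GenomicRanges::GRanges()
  } else {
    gtf <- tryCatch(
      rtracklayer::import(annotation_path, format = "gtf"),
      error = function(e) stop("GTF parse error in ", annotation_path, ": ",
                               conditionMessage(e), call. = FALSE))
  }
  if (length(gtf) == 0) {
    return(gene_set(
      GenomicRanges::GRanges(gene_id = character(), biotype = character(),
                             tss = integer(), final_tss = integer(),
                             pas = integer(), exonic_length = integer()),
      GenomicRanges::GRangesList(), chrom_sizes = genome_sizes))
  }
  ex <- gtf[gtf$type == "exon"]
  if (length(ex) == 0) stop("GTF contains no exon features")
  if (is.null(ex$gene_id)) stop("GTF exons lack gene_id attribute")
  if (is.null(ex$transcript_id)) ex$transcript_id <- ex$gene_id
  if (is.null(ex$gene_biotype)) ex$gene_biotype <- "other"
  if (!is.null(genome_sizes)) {
    bad <- setdiff(as.character(unique(GenomicRanges::seqnames(ex))),
                   names(genome_sizes))
    if (length(bad)) stop("exon on unknown chromosome(s): ",
                          paste(bad, collapse = ", "))
  }

  id <- as.character(ex$gene_id)
  chr <- as.character(GenomicRanges::seqnames(ex))
  str <- as.character(GenomicRanges::strand(ex))
  one <- function(v) tapply(v, id, function(x) length(unique(x)) == 1L)
  ok_chr <- one(chr); ok_str <- one(str) & tapply(str, id, function(s)
    all(s %in% c("+", "-")))
  bad_ids <- names(ok_chr)[!(ok_chr & ok_str)]
  if (length(bad_ids)) {
    warning("dropping ", length(bad_ids),
            " gene(s) with exons on multiple chromosomes/strands: ",
            paste(utils::head(bad_ids, 5), collapse = ", "),
            if (length(bad_ids) > 5) ", ..." else "")
    keep <- !(id %in% bad_ids)
    ex <- ex[keep]; id <- id[keep]
  }
  if (length(ex) == 0) stop("no genes left after strand/chromosome filtering")

  exl <- GenomicRanges::reduce(S4Vectors::split(GenomicRanges::granges(ex), id))
  ids <- names(exl)

  # per-transcript extremes -> tss / final_tss / pas
  txid <- paste(id, as.character(ex$transcript_id), sep = "\r")
  tx_start <- tapply(GenomicRanges::start(ex), txid, min)
  tx_end <- tapply(GenomicRanges::end(ex), txid, max)
  tx_gene <- sub("\r.*$", "", names(tx_start))

  first <- !duplicated(id)
  meta <- data.frame(gene_id = id[first],
                     chrom = chr_of <- as.character(GenomicRanges::seqnames(ex))[first],
                     strand = as.character(GenomicRanges::strand(ex))[first],
                     biotype = biotype_class(as.character(ex$gene_biotype)[first]),
                     stringsAsFactors = FALSE)
  meta <- meta[match(ids, meta$gene_id), ]

  g_start <- tapply(GenomicRanges::start(ex), id, min)[ids]
  g_end <- tapply(GenomicRanges::end(ex), id, max)[ids]
  plus <- meta$strand == "+"
  agg <- function(f, v) tapply(v, tx_gene, f)[ids]
  tss <- ifelse(plus, agg(min, tx_start), agg(max, tx_end))
  final_tss <- ifelse(plus, agg(max, tx_start), agg(min, tx_end))
  pas <- ifelse(plus, agg(max, tx_end), agg(min, tx_start))

  genes <- GenomicRanges::GRanges(meta$chrom,
                                  IRanges::IRanges(g_start, g_end),
                                  strand = meta$strand)
  genes$gene_id <- meta$gene_id
  genes$biotype <- meta$biotype
  genes$tss <- as.integer(tss)
  genes$final_tss <- as.integer(final_tss)
  genes$pas <- as.integer(pas)
  genes$exonic_length <- as.integer(sum(GenomicRanges::width(exl)))[match(ids, names(exl))]
  gene_set(genes, exl, chrom_sizes = genome_sizes)
}

#' Exon mask for one strand
#'
#' Union of all annotated exon intervals on the requested strand. Background
#' estimation masks these bases out so that local background reflects
#' intronic and intergenic transcription only.
#'
#' @param gs a `GeneSet`.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `ExonMask`.
#' @export
build_exon_mask <- function(gs, strand) {
  stopifnot(strand %in% c("+", "-"))
  ex <- unlist(gs$exons, use.names = FALSE)
  ex <- ex[as.character(GenomicRanges::strand(ex)) == strand]
  ranges <- GenomicRanges::reduce(GenomicRanges::granges(ex),
                                  ignore.strand = TRUE)
  # per-chromosome sorted disjoint intervals for binary-search queries
  idx <- lapply(split(ranges, as.character(GenomicRanges::seqnames(ranges))),
                function(r) list(starts = GenomicRanges::start(r),
                                 ends = GenomicRanges::end(r)))
  structure(list(ranges = ranges, strand = strand, idx = idx),
            class = "ExonMask")
}

# complement of the mask within [lo, hi] on one chromosome: matrix with
# columns start, end (possibly 0 rows)
mask_complement <- function(mask, chrom, lo, hi) {
  slot <- mask$idx[[chrom]]
  if (is.null(slot) || length(slot$starts) == 0)
    return(cbind(start = lo, end = hi))
  i1 <- findInterval(lo - 1, slot$ends) + 1L       # first with end >= lo
  i2 <- findInterval(hi, slot$starts)              # last with start <= hi
  if (i2 < i1) return(cbind(start = lo, end = hi))
  ms <- pmax(slot$starts[i1:i2], lo)
  me <- pmin(slot$ends[i1:i2], hi)
  starts <- c(lo, me + 1)
  ends <- c(ms - 1, hi)
  keep <- ends >= starts
  cbind(start = starts[keep], end = ends[keep])
}

#' Unmasked size of query intervals
#'
#' @param mask an `ExonMask`.
#' @param intervals `GRanges` of query intervals.
#' @return Integer vector: bases of each query not covered by the mask.
#' @export
masked_size <- function(mask, intervals) {
  if (length(intervals) == 0) return(integer())
  chrom <- as.character(GenomicRanges::seqnames(intervals))
  lo <- GenomicRanges::start(intervals)
  hi <- GenomicRanges::end(intervals)
  vapply(seq_along(intervals), function(i) {
    if (hi[i] < lo[i]) return(0L)
    p <- mask_complement(mask, chrom[i], lo[i], hi[i])
    as.integer(sum(p[, "end"] - p[, "start"] + 1))
  }, integer(1))
}

#' Unmasked sub-intervals of query windows
#'
#' @param mask an `ExonMask`.
#' @param intervals `GRanges` query windows.
#' @return `GRanges` of unmasked parts with a metadata column `window` giving
#'   the index of the originating query.
#' @keywords internal
unmasked_parts <- function(mask, intervals) {
  if (length(intervals) == 0) return(GenomicRanges::GRanges(window = integer()))
  parts <- lapply(seq_along(intervals), function(i) {
    p <- GenomicRanges::setdiff(GenomicRanges::granges(intervals[i]),
                                mask$ranges, ignore.strand = TRUE)
    p$window <- rep(i, length(p))
    p
  })
  out <- suppressWarnings(do.call(c, parts))
  out
}

clamp_positions <- function(start, end, chrom, chrom_sizes) {
  start <- pmax(start, 1)
  if (!is.null(chrom_sizes)) {
    lim <- unname(chrom_sizes[as.character(chrom)])
    lim[is.na(lim)] <- Inf
    end <- pmin(end, lim)
  }
  list(start = start, end = pmax(end, start - 1))  # allow zero width
}

#' Promoter regions
#'
#' Strand-aware window around each TSS, by default 5 kb upstream and 1 kb
#' downstream, truncated at chromosome bounds.
#'
#' @param gs a `GeneSet`.
#' @param up bases upstream of the TSS (default 5000).
#' @param down bases downstream of the TSS (default 1000).
#' @param gene_ids optional subset of gene ids.
#' @return `GRanges` named by gene id, same strand as the gene.
#' @export
promoter_region <- function(gs, up = 5000, down = 1000, gene_ids = NULL) {
  g <- gs$genes
  if (!is.null(gene_ids)) g <- g[match(gene_ids, g$gene_id)]
  plus <- as.character(GenomicRanges::strand(g)) == "+"
  # the TSS base itself counts as the first downstream base
  s <- ifelse(plus, g$tss - up, g$tss - down + 1)
  e <- ifelse(plus, g$tss + down - 1, g$tss + up)
  cl <- clamp_positions(s, e, GenomicRanges::seqnames(g), gs$chrom_sizes)
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(g),
                                IRanges::IRanges(cl$start, cl$end),
                                strand = GenomicRanges::strand(g))
  names(out) <- g$gene_id
  out
}

#' Upstream search windows for udRNA detection
#'
#' Strand-aware window of `length` bases ending immediately upstream of the
#' TSS (the TSS base itself is excluded), truncated at chromosome bounds.
#' The window is reported on the strand opposite to the gene, because that
#' is where upstream divergent transcription is sought.
#'
#' @param gs a `GeneSet`.
#' @param length window size in bases (default 5000).
#' @param gene_ids optional subset of gene ids.
#' @return `GRanges` named by gene id, strand opposite to the gene.
#' @export
upstream_window <- function(gs, length = 5000, gene_ids = NULL) {
  g <- gs$genes
  if (!is.null(gene_ids)) g <- g[match(gene_ids, g$gene_id)]
  plus <- as.character(GenomicRanges::strand(g)) == "+"
  s <- ifelse(plus, g$tss - length, g$tss + 1)
  e <- ifelse(plus, g$tss - 1, g$tss + length)
  cl <- clamp_positions(s, e, GenomicRanges::seqnames(g), gs$chrom_sizes)
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(g),
                                IRanges::IRanges(cl$start, cl$end),
                                strand = ifelse(plus, "-", "+"))
  names(out) <- g$gene_id
  out
}

#' Gene universe for overlap analyses
#'
#' Protein-coding and lincRNA genes with interval length above a minimum
#' (default 1 kb), the restriction used for all feature-overlap statistics.
#'
#' @param gs a `GeneSet`.
#' @param min_length minimum gene interval length in bases.
#' @return Character vector of gene ids.
#' @export
overlap_universe <- function(gs, min_length = 1000) {
  g <- gs$genes
  keep <- g$biotype %in% c("protein_coding", "lincRNA") &
    GenomicRanges::width(g) > min_length
  g$gene_id[keep]
}
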