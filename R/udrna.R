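#' Genes eligible for the udRNA search
#'
#' Protein-coding genes, excluding members of closely spaced divergently
#' oriented protein-coding pairs (head-to-head TSSs on opposite strands
#' within `min_gap` of each other), whose upstream reads cannot be
#' disentangled from the neighbour's.
#'
#' @param gs a `GeneSet`.
#' @param min_gap maximum TSS-to-TSS distance of an excluding divergent
#'   pair, in bases (default 10000).
#' @return Character vector of eligible gene ids.
#' @export
eligible_genes <- function(gs, min_gap = 10000) {
  g <- gs$genes[gs$genes$biotype == "protein_coding"]
  if (length(g) == 0) return(character())
  chrom <- as.character(GenomicRanges::seqnames(g))
  strand <- as.character(GenomicRanges::strand(g))
  tss <- g$tss
  excluded <- logical(length(g))
  for (ch in unique(chrom)) {
    i_plus <- which(chrom == ch & strand == "+")
    i_minus <- which(chrom == ch & strand == "-")
    if (!length(i_plus) || !length(i_minus)) next
    # divergent head-to-head: the minus gene's TSS lies upstream (left) of
    # the plus gene's TSS, promoters back to back
    dd <- outer(tss[i_plus], tss[i_minus], `-`)
    close <- dd >= 0 & dd < min_gap
    excluded[i_plus[rowSums(close) > 0]] <- TRUE
    excluded[i_minus[colSums(close) > 0]] <- TRUE
  }
  g$gene_id[!excluded]
}

#' udRNA detection threshold
#'
#' The normalized-count threshold a putative udRNA region must reach:
#' `max(10, 2 * window_size * max_j(c_j / d_j))`, i.e. a floor of 10
#' uniquely mapped reads and at least two-fold the densest of the five
#' downstream antisense background windows scaled to the search window
#' size. With no retained background window the floor alone applies.
#'
#' @param bg a `BackgroundEstimate` from
#'   [downstream_antisense_background()].
#' @param window_size size of the udRNA search window in bases (default
#'   5000; pass the actual truncated width for windows clamped at a
#'   chromosome edge).
#' @param min_count the floor (default 10 normalized reads).
#' @param bg_factor the fold-over-background factor (default 2).
#' @return Normalized-count threshold.
#' @export
udrna_threshold <- function(bg, window_size = 5000, min_count = 10,
                            bg_factor = 2) {
  if (length(bg$a) == 0) return(min_count)
  max(min_count, bg_factor * window_size * max(bg$a / bg$b))
}

#' Detect upstream divergent RNA transcription units
#'
#' For each eligible protein-coding gene, counts normalized reads on the
#' opposite strand in the 5 kb window immediately upstream of the TSS, per
#' sample, and emits a call when at least one sample reaches its
#' per-sample threshold (floor of 10 normalized reads and two-fold over
#' each downstream antisense background window). Detection uses an equal
#' number of control and knockdown samples to avoid biasing the catalogue
#' toward either condition.
#'
#' @param gs a `GeneSet`.
#' @param ctrl_sets,kd_sets lists of `StrandedReadSet`s; must be the same
#'   length unless `allow_unbalanced = TRUE`.
#' @param nf a `NormalizationFactors` object covering all samples used.
#' @param upstream_len search window length in bases (default 5000).
#' @param min_count threshold floor (default 10).
#' @param bg_factor fold-over-background factor (default 2).
#' @param min_gap divergent-pair exclusion distance (default 10000).
#' @param allow_unbalanced override the balance requirement (logged with a
#'   warning).
#' @return data.frame of class `UdRNACall`: one row per detected udRNA
#'   with region coordinates (opposite strand), per-sample normalized
#'   counts and thresholds as attribute matrices, `threshold_used` and
#'   `detected_in`.
#' @export
detect_udrnas <- function(gs, ctrl_sets, kd_sets, nf, upstream_len = 5000,
                          min_count = 10, bg_factor = 2, min_gap = 10000,
                          allow_unbalanced = FALSE) {
  if (length(ctrl_sets) != length(kd_sets)) {
    if (!allow_unbalanced)
      stop("detection requires equal numbers of control and knockdown ",
           "samples (override with allow_unbalanced = TRUE)")
    warning("unbalanced control/knockdown sample sets used for detection")
  }
  sets <- c(ctrl_sets, kd_sets)
  names(sets) <- vapply(sets, function(x) x$sample_id, character(1))
  ids <- eligible_genes(gs, min_gap)
  if (!length(ids)) return(empty_udrna_calls())
  win <- upstream_window(gs, length = upstream_len, gene_ids = ids)
  keep <- GenomicRanges::width(win) > 0
  ids <- ids[keep]; win <- win[keep]
  gstr <- as.character(GenomicRanges::strand(gs$genes))[
    match(ids, gs$genes$gene_id)]
  anti <- ifelse(gstr == "+", "-", "+")
  masks <- list("+" = build_exon_mask(gs, "+"),
                "-" = build_exon_mask(gs, "-"))
  geoms <- lapply(seq_along(ids), function(i)
    bg_geometry(gs, ids[i], "downstream_antisense", masks[[anti[i]]]))

  counts <- thresholds <- matrix(
    NA_real_, length(ids), length(sets),
    dimnames = list(ids, names(sets)))
  chroms <- as.character(GenomicRanges::seqnames(win))
  ws <- GenomicRanges::start(win); we <- GenomicRanges::end(win)
  for (s in names(sets)) {
    pp <- read_pool(sets[[s]])
    sc <- norm_scale(nf, s)
    for (i in seq_along(ids)) {
      counts[i, s] <- pool_count(pp, chroms[i], anti[i], ws[i], we[i]) * sc
      geom <- geoms[[i]]
      bg <- list(a = bg_count(geom, pp, sc), b = geom$b)
      thresholds[i, s] <- udrna_threshold(
        bg, window_size = GenomicRanges::width(win)[i],
        min_count = min_count, bg_factor = bg_factor)
    }
  }
  pass <- counts >= thresholds
  hit <- rowSums(pass) > 0
  out <- data.frame(
    gene_id = ids[hit],
    chrom = as.character(GenomicRanges::seqnames(win))[hit],
    start = GenomicRanges::start(win)[hit],
    end = GenomicRanges::end(win)[hit],
    strand = anti[hit],
    threshold_used = vapply(which(hit), function(i)
      min(thresholds[i, pass[i, ]]), numeric(1)),
    detected_in = vapply(which(hit), function(i)
      paste(colnames(pass)[pass[i, ]], collapse = ","), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "counts") <- counts[hit, , drop = FALSE]
  attr(out, "thresholds") <- thresholds[hit, , drop = FALSE]
  attr(out, "screened") <- ids
  class(out) <- c("UdRNACall", "data.frame")
  out
}

empty_udrna_calls <- function() {
  out <- data.frame(gene_id = character(), chrom = character(),
                    start = integer(), end = integer(), strand = character(),
                    threshold_used = numeric(), detected_in = character(),
                    stringsAsFactors = FALSE)
  class(out) <- c("UdRNACall", "data.frame")
  out
}

#' Quantify the knockdown response of udRNA regions
#'
#' Region-level log2 fold change of normalized antisense counts (all
#' knockdown samples vs all controls, pseudocount 1); a udRNA is flagged
#' regulated when the pseudocounted fold change exceeds `regulated_fold`.
#'
#' @param calls a `UdRNACall` table from [detect_udrnas()].
#' @param kd_sets,ctrl_sets lists of `StrandedReadSet`s (all samples, not
#'   just the detection subset).
#' @param nf a `NormalizationFactors` object.
#' @param pseudocount pseudocount (default 1).
#' @param regulated_fold linear fold-change threshold for the regulated
#'   flag (default 2).
#' @return The call table with added columns `mean_kd`, `mean_ctrl`,
#'   `log2fc`, `regulated`.
#' @export
quantify_udrna_response <- function(calls, kd_sets, ctrl_sets, nf,
                                    pseudocount = 1, regulated_fold = 2) {
  if (nrow(calls) == 0) {
    calls$mean_kd <- calls$mean_ctrl <- calls$log2fc <- numeric(0)
    calls$regulated <- logical(0)
    return(calls)
  }
  regions <- GenomicRanges::GRanges(calls$chrom,
                                    IRanges::IRanges(calls$start, calls$end),
                                    strand = calls$strand)
  grp_mean <- function(sets) {
    m <- vapply(sets, function(rs)
      count_region_reads(rs, regions) * norm_scale(nf, rs$sample_id),
      numeric(length(regions)))
    rowMeans(matrix(m, nrow = length(regions)))
  }
  mk <- grp_mean(kd_sets); mc <- grp_mean(ctrl_sets)
  fc <- (mk + pseudocount) / (mc + pseudocount)
  calls$mean_kd <- mk
  calls$mean_ctrl <- mc
  calls$log2fc <- log2(fc)
  calls$regulated <- fc > regulated_fold
  calls
}
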