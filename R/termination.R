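# flank interval of up to max_len bases next to `edge`, truncated at
# chromosome bounds but keeping the width a multiple of `bin` so the bin
# grid stays anchored at the gene edge; NULL if no full bin fits
anchored_flank <- function(side, edge, max_len, bin, chrom, chrom_sizes) {
  if (side == "left") {
    lo0 <- max(1, edge - max_len)
    nb <- floor((edge - lo0) / bin)
    if (nb < 1) return(NULL)
    list(start = edge - nb * bin, end = edge - 1, n_bins = nb)
  } else {
    hi0 <- edge + max_len
    if (!is.null(chrom_sizes)) {
      lim <- unname(chrom_sizes[as.character(chrom)])
      if (!is.na(lim)) hi0 <- min(hi0, lim)
    }
    nb <- floor((hi0 - edge) / bin)
    if (nb < 1) return(NULL)
    list(start = edge + 1, end = edge + nb * bin, n_bins = nb)
  }
}

#' Gene-body and flank density vectors
#'
#' Subdivides the gene body into `body_bins` equal bins and the flanking
#' regions into `flank_bins` bins of `flank_bin` bases each, and computes
#' normalized read density (reads per base) per bin on the gene's strand.
#' Vectors are strand-oriented: body bin 1 is at the TSS; downstream bin 1
#' abuts the PAS; upstream bin 1 abuts the TSS walking away from the gene.
#' Flanks truncated at chromosome bounds keep the bins that fit.
#'
#' @param gs a `GeneSet`.
#' @param gene_id gene identifier.
#' @param rs a `StrandedReadSet`.
#' @param scale normalization multiplier for the sample (default 1).
#' @param body_bins number of gene-body bins (default 100).
#' @param flank_bins number of flank bins (default 500).
#' @param flank_bin flank bin size in bases (default 200).
#' @return List with `DensityVector`s `body`, `upstream`, `downstream`, or
#'   `NULL` (with a warning) for genes shorter than `body_bins` bases.
#' @export
bin_gene_and_flanks <- function(gs, gene_id, rs, scale = 1, body_bins = 100,
                                flank_bins = 500, flank_bin = 200) {
  g <- gs$genes[match(gene_id, gs$genes$gene_id)]
  if (GenomicRanges::width(g) < body_bins) {
    warning("gene ", gene_id, " shorter than ", body_bins, " bases; skipped")
    return(NULL)
  }
  strand <- as.character(GenomicRanges::strand(g))
  chrom <- as.character(GenomicRanges::seqnames(g))
  flank <- flank_bins * flank_bin

  body <- bin_density(rs, GenomicRanges::granges(g), strand,
                      n_bins = body_bins, scale = scale)
  s <- GenomicRanges::start(g); e <- GenomicRanges::end(g)
  left <- anchored_flank("left", s, flank, flank_bin, chrom,
                         gs$chrom_sizes)
  right <- anchored_flank("right", e, flank, flank_bin, chrom,
                          gs$chrom_sizes)
  mk <- function(cl) {
    if (is.null(cl)) return(NULL)
    bin_density(rs, GenomicRanges::GRanges(chrom,
                                           IRanges::IRanges(cl$start, cl$end)),
                strand, bin_size = flank_bin, scale = scale)
  }
  left_dv <- mk(left); right_dv <- mk(right)
  orient <- function(dv, reverse) {
    if (is.null(dv)) {
      dv <- list(density = numeric(0), counts = numeric(0),
                 bin_size = flank_bin, n_bins = 0)
    } else if (reverse) {
      dv$density <- rev(dv$density); dv$counts <- rev(dv$counts)
    }
    dv
  }
  if (strand == "+") {
    upstream <- orient(left_dv, reverse = TRUE)   # bin 1 nearest the TSS
    downstream <- orient(right_dv, reverse = FALSE)
  } else {
    if (!is.null(body)) {
      body$density <- rev(body$density); body$counts <- rev(body$counts)
    }
    upstream <- orient(right_dv, reverse = FALSE)
    downstream <- orient(left_dv, reverse = TRUE)
  }
  list(body = body, upstream = upstream, downstream = downstream)
}

#' Find enrichment regions in a density vector
#'
#' A bin qualifies if any sliding window of `window` consecutive bins
#' containing it has mean density of at least `min_density`; maximal runs
#' of qualifying bins become regions. Regions whose own mean density falls
#' below `min_density` are flagged low-support (a single hot bin can smear
#' across its covering windows). Vectors shorter than `window` are treated
#' as a single window.
#'
#' @param density numeric vector of per-bin densities.
#' @param min_density minimum mean window density (default 0.005, i.e. an
#'   average normalized count of 1 in a 200 bp bin).
#' @param window sliding window length in bins (default 10).
#' @return data.frame with `start_bin`, `end_bin`, `n_bins`,
#'   `mean_density`, `low_support`.
#' @export
find_enrichment_regions <- function(density, min_density = 0.005,
                                    window = 10) {
  n <- length(density)
  empty <- data.frame(start_bin = integer(), end_bin = integer(),
                      n_bins = integer(), mean_density = numeric(),
                      low_support = logical())
  if (n == 0) return(empty)
  w <- min(window, n)
  cs <- cumsum(c(0, density))
  wm <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w  # mean of bins i..i+w-1
  hot <- wm >= min_density
  qual <- logical(n)
  for (i in which(hot)) qual[i:(i + w - 1)] <- TRUE
  if (!any(qual)) return(empty)
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  out <- data.frame(start_bin = starts[keep], end_bin = ends[keep])
  out$n_bins <- out$end_bin - out$start_bin + 1
  out$mean_density <- vapply(seq_len(nrow(out)), function(i)
    mean(density[out$start_bin[i]:out$end_bin[i]]), numeric(1))
  out$low_support <- out$mean_density < min_density
  out
}

#' Region-level log2 fold change per ASO pair
#'
#' Log2 ratio of the mean of each knockdown sample pair to the mean of the
#' control pair, after flooring every count at 1 (so empty regions give a
#' fold change of 0 rather than an undefined ratio).
#'
#' @param region_counts named numeric vector (or 1-row matrix) of
#'   normalized region counts, names matching `design$sample_id`.
#' @param design a `SampleDesign`.
#' @param floor count floor (default 1).
#' @return Named numeric vector `c(anti_7sk_5p = ..., anti_7sk_3p = ...)`.
#' @export
region_log2fc <- function(region_counts, design, floor = 1) {
  x <- pmax(unlist(region_counts), floor)
  if (!all(design$sample_id %in% names(x)))
    stop("missing sample counts: ",
         paste(setdiff(design$sample_id, names(x)), collapse = ", "))
  ctrl <- mean(x[design$sample_id[design$aso == "scrambled"]])
  vapply(c("anti_7sk_5p", "anti_7sk_3p"), function(a)
    log2(mean(x[design$sample_id[design$aso == a]]) / ctrl), numeric(1))
}

#' Call readthrough candidates
#'
#' Potential candidates show a downstream region of enrichment larger than
#' `min_potential` with a fold change above `fc_threshold` in at least one
#' ASO pair (`require_both` switches to both). Candidates are additionally
#' actively transcribed, have a downstream region larger than
#' `min_candidate`, and show no potential candidate on the same strand
#' whose PAS lies within `lookback` bases upstream of their TSS (such an
#' upstream locus is the more likely origin of the signal).
#'
#' @param gs a `GeneSet`.
#' @param region_tbl data.frame with columns `gene_id`, `size` (downstream
#'   region size in bases; NA or 0 when absent), `fc_5p`, `fc_3p`.
#' @param expressed named logical vector: actively transcribed flag per
#'   gene.
#' @param fc_threshold linear fold-change threshold (default 1.5).
#' @param min_potential minimum region size for potential candidates in
#'   bases (default 1000, exclusive).
#' @param min_candidate minimum region size for candidates in bases
#'   (default 3000, exclusive).
#' @param lookback upstream search distance in bases (default 100000).
#' @param require_both require the fold-change criterion in both ASO pairs
#'   (default FALSE: either).
#' @return `region_tbl` with logical columns `is_potential`,
#'   `is_candidate` and `has_upstream_potential`.
#' @export
call_readthrough_candidates <- function(gs, region_tbl, expressed,
                                        fc_threshold = 1.5,
                                        min_potential = 1000,
                                        min_candidate = 3000,
                                        lookback = 100000,
                                        require_both = FALSE) {
  lfc <- log2(fc_threshold)
  size <- ifelse(is.na(region_tbl$size), 0, region_tbl$size)
  fc_ok <- if (require_both)
    region_tbl$fc_5p > lfc & region_tbl$fc_3p > lfc
  else
    pmax(region_tbl$fc_5p, region_tbl$fc_3p, na.rm = TRUE) > lfc
  fc_ok[is.na(fc_ok)] <- FALSE
  region_tbl$is_potential <- size > min_potential & fc_ok

  g <- gs$genes[match(region_tbl$gene_id, gs$genes$gene_id)]
  chrom <- as.character(GenomicRanges::seqnames(g))
  strand <- as.character(GenomicRanges::strand(g))
  tss <- g$tss; pas <- g$pas
  pot <- which(region_tbl$is_potential)
  upstream_pot <- logical(nrow(region_tbl))
  for (i in seq_len(nrow(region_tbl))) {
    js <- pot[pot != i & chrom[pot] == chrom[i] & strand[pot] == strand[i]]
    if (!length(js)) next
    d <- if (strand[i] == "+") tss[i] - pas[js] else pas[js] - tss[i]
    upstream_pot[i] <- any(d >= 0 & d <= lookback)
  }
  region_tbl$has_upstream_potential <- upstream_pot
  expr <- expressed[region_tbl$gene_id]
  expr[is.na(expr)] <- FALSE
  region_tbl$is_candidate <- region_tbl$is_potential & unname(expr) &
    size > min_candidate & !upstream_pot
  region_tbl
}

#' Deterministic change-point segmentation (piecewise-constant mean)
#'
#' Binary segmentation minimizing within-segment residual sum of squares
#' with a BIC-style penalty. Splits are accepted while the RSS reduction
#' exceeds `penalty_mult * sigma^2 * log(n)`, with `sigma` estimated
#' robustly from first differences (so a noiseless step signal is
#' recovered exactly).
#'
#' @param x numeric vector.
#' @param penalty_mult penalty multiplier (default 3).
#' @param max_changepoints cap on the number of change points (default 60).
#' @param min_segment minimum segment length in bins (default 5); guards
#'   against single sparse bins fragmenting an otherwise contiguous
#'   signal.
#' @return data.frame with `start`, `end`, `mean` per segment, in order.
#' @export
segment_piecewise_mean <- function(x, penalty_mult = 3,
                                   max_changepoints = 60,
                                   min_segment = 5) {
  n <- length(x)
  if (n == 0) return(data.frame(start = integer(), end = integer(),
                                mean = numeric()))
  sigma2 <- (stats::mad(diff(x)) / sqrt(2))^2
  pen <- max(penalty_mult * sigma2 * log(n), 1e-12)
  cs <- cumsum(x)
  # best split of [l, r]: maximal RSS gain over interior split points
  best_split <- function(l, r) {
    if (r - l + 1 < 2 * min_segment) return(c(NA, -Inf))
    m <- (l + min_segment - 1):(r - min_segment)
    sL <- cs[m] - if (l > 1) cs[l - 1] else 0
    nL <- m - l + 1
    sR <- (cs[r] - cs[m])
    nR <- r - m
    gain <- sL^2 / nL + sR^2 / nR - (sL + sR)^2 / (nL + nR)
    k <- which.max(gain)
    c(m[k], gain[k])
  }
  segs <- list(c(1, n))
  repeat {
    if (length(segs) > max_changepoints) break
    cand <- vapply(segs, function(s) best_split(s[1], s[2]), numeric(2))
    k <- which.max(cand[2, ])
    if (!is.finite(cand[2, k]) || cand[2, k] <= pen) break
    s <- segs[[k]]; m <- cand[1, k]
    segs[[k]] <- c(s[1], m)
    segs[[length(segs) + 1]] <- c(m + 1, s[2])
  }
  segs <- segs[order(vapply(segs, `[`, numeric(1), 1))]
  data.frame(start = vapply(segs, `[`, numeric(1), 1),
             end = vapply(segs, `[`, numeric(1), 2),
             mean = vapply(segs, function(s) mean(x[s[1]:s[2]]), numeric(1)))
}

#' Estimate readthrough extent by change-point segmentation
#'
#' Segments the downstream per-bin density vector (typically 200 bp bins
#' over 1 Mb from the PAS) into piecewise-constant segments, then merges
#' contiguous segments from the PAS outward while their mean density
#' exceeds `min_segment_density`. The extent is the distance from the PAS
#' to the end of the merged run; 0 if the first segment already fails.
#'
#' @param density strand-oriented downstream density vector (bin 1 abuts
#'   the PAS).
#' @param bin_size bin size in bases (default 200).
#' @param min_segment_density merge threshold on segment mean density
#'   (default 0.01, strict).
#' @param ... passed to [segment_piecewise_mean()].
#' @return List with `extent` (bases), `n_bins` merged, and the segment
#'   table.
#' @export
estimate_readthrough_extent <- function(density, bin_size = 200,
                                        min_segment_density = 0.01, ...) {
  segs <- segment_piecewise_mean(density, ...)
  last <- 0
  for (i in seq_len(nrow(segs))) {
    if (segs$mean[i] > min_segment_density) last <- segs$end[i] else break
  }
  # the minimum segment length limits the boundary resolution; refine the
  # merged end to single-bin precision with a local two-segment fit
  if (last > 0 && last < length(density))
    last <- refine_boundary(density, last)
  list(extent = last * bin_size, n_bins = last, segments = segs)
}

# best single change point (by RSS) within +-halfwidth bins of E
refine_boundary <- function(x, E, halfwidth = 6) {
  lo <- max(1, E - halfwidth); hi <- min(length(x), E + halfwidth)
  if (hi - lo < 2) return(E)
  xs <- x[lo:hi]
  m <- length(xs)
  cs <- cumsum(xs)
  b <- seq_len(m - 1)
  gain <- cs[b]^2 / b + (cs[m] - cs[b])^2 / (m - b)
  lo + which.max(gain) - 1
}

#' Order candidate genes for a readthrough heatmap
#'
#' Combines the per-sample normalized read distributions about the PAS into
#' a single average fold-change per gene and orders genes from highest to
#' lowest (ties broken by gene id), the display order of the readthrough
#' heatmap.
#'
#' @param candidate_tbl data.frame with `gene_id`, `fc_5p`, `fc_3p`.
#' @param density_matrix optional genes x bins matrix (rownames = gene ids)
#'   of combined densities about the PAS; reordered alongside.
#' @return List with `gene_id` (ordered), `avg_fc`, and `matrix`
#'   (reordered or NULL).
#' @export
order_genes_for_heatmap <- function(candidate_tbl, density_matrix = NULL) {
  avg <- rowMeans(cbind(candidate_tbl$fc_5p, candidate_tbl$fc_3p),
                  na.rm = TRUE)
  ord <- order(-avg, candidate_tbl$gene_id)
  ids <- candidate_tbl$gene_id[ord]
  m <- if (!is.null(density_matrix))
    density_matrix[match(ids, rownames(density_matrix)), , drop = FALSE]
  list(gene_id = ids, avg_fc = avg[ord], matrix = m)
}
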