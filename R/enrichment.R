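#' Feature overlap flags
#'
#' Flags each region that overlaps a feature by at least `min_overlap`
#' bases. Overlap is strand-agnostic unless `stranded = TRUE`, in which
#' case only same-strand feature overlaps count.
#'
#' @param regions `GRanges` of query regions.
#' @param features `GRanges` of features (e.g. H3K4me3 domains, engaged
#'   Pol II regions).
#' @param min_overlap minimum overlapping bases (default 1).
#' @param stranded require matching strand (default FALSE).
#' @return Logical vector, one flag per region.
#' @export
overlap_features <- function(regions, features, min_overlap = 1,
                             stranded = FALSE) {
  if (length(features) == 0) return(rep(FALSE, length(regions)))
  al <- align_seqlevels(regions, features)
  GenomicRanges::countOverlaps(al$a, al$b,
                               minoverlap = min_overlap,
                               ignore.strand = !stranded) > 0
}

#' Fisher's exact test on a 2 x 2 contingency table
#'
#' Two-sided exact p-value: the sum of hypergeometric point probabilities
#' not exceeding that of the observed table (the standard exact-test
#' convention), plus the sample odds ratio `(a d) / (b c)` (reported as
#' the boundary value when a margin cell is zero).
#'
#' @param a,b,c,d the table cells: in-set with feature, in-set without,
#'   out-set with, out-set without. Alternatively pass a 2 x 2 matrix as
#'   `a`.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return List with `odds_ratio`, `p`, and the table.
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL,
                         alternative = "two.sided") {
  if (is.matrix(a)) {
    m <- a
  } else {
    m <- matrix(c(a, c, b, d), 2, 2)
  }
  if (any(m < 0)) stop("contingency table cells must be non-negative")
  if (any(m != round(m))) stop("contingency table cells must be integers")
  ft <- stats::fisher.test(m, alternative = alternative)
  or <- (m[1, 1] * m[2, 2]) / (m[2, 1] * m[1, 2])  # sample odds ratio
  list(odds_ratio = or, p = unname(ft$p.value), table = m)
}

#' Randomization test for a group's average expression change
#'
#' The statistic is the geometric mean over the group of per-gene
#' pseudocounted expression ratios (knockdown over control, typically on
#' background-adjusted data). The null draws random same-size gene sets
#' from the universe; the p-value uses the add-one correction
#' `(1 + #{null >= observed}) / (n_perm + 1)` and so never returns 0.
#'
#' @param group gene ids of the tested group (subset of `universe`).
#' @param universe gene ids of the sampling universe.
#' @param ratios named per-gene expression ratios (linear scale, already
#'   pseudocounted).
#' @param n_perm number of permutations (>= 1).
#' @param seed random seed (required, for reproducibility).
#' @return List with `observed` (geometric-mean ratio), `p`, `n_perm`.
#' @export
group_fc_randomization <- function(group, universe, ratios, n_perm, seed) {
  if (length(group) == 0) stop("group must be non-empty")
  if (!all(group %in% universe)) stop("group must be a subset of universe")
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (missing(seed)) stop("seed is required")
  gmean <- function(ids) exp(mean(log(ratios[ids])))
  obs <- gmean(group)
  null <- local_seed(seed, {
    vapply(seq_len(n_perm), function(i)
      gmean(sample(universe, length(group))), numeric(1))
  })
  list(observed = unname(obs),
       p = (1 + sum(null >= obs)) / (n_perm + 1),
       n_perm = n_perm)
}

# evaluate expr under a temporary RNG state
local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Local gene density around an anchor position
#'
#' Number of distinct other genes (protein-coding and lincRNA longer than
#' `min_length`) overlapping a window of +/- `window` bases around each
#' gene's anchor (by default its PAS).
#'
#' @param gs a `GeneSet`.
#' @param anchors optional named vector of anchor positions; defaults to
#'   each gene's PAS.
#' @param window half-width in bases (default 100000).
#' @param min_length minimum neighbour gene length (default 1000,
#'   exclusive).
#' @return Named integer vector of neighbour counts per gene.
#' @export
gene_density <- function(gs, anchors = NULL, window = 100000,
                         min_length = 1000) {
  g <- gs$genes
  if (is.null(anchors)) anchors <- stats::setNames(g$pas, g$gene_id)
  uni <- g[g$biotype %in% c("protein_coding", "lincRNA") &
             GenomicRanges::width(g) > min_length]
  ids <- names(anchors)
  gg <- g[match(ids, g$gene_id)]
  cl <- clamp_positions(anchors - window, anchors + window,
                        GenomicRanges::seqnames(gg), gs$chrom_sizes)
  win <- GenomicRanges::GRanges(GenomicRanges::seqnames(gg),
                                IRanges::IRanges(cl$start, cl$end))
  hits <- GenomicRanges::findOverlaps(win, uni, ignore.strand = TRUE)
  self <- uni$gene_id[S4Vectors::subjectHits(hits)] ==
    ids[S4Vectors::queryHits(hits)]
  tab <- table(factor(S4Vectors::queryHits(hits)[!self],
                      levels = seq_along(ids)))
  stats::setNames(as.integer(tab), ids)
}

#' Pair genes with divergent lncRNAs
#'
#' A gene is associated with divergent lncRNA transcription when the 1 kb
#' region immediately upstream of its TSS intersects a lncRNA locus on the
#' opposite strand.
#'
#' @param gs a `GeneSet`.
#' @param lncrna_loci stranded `GRanges` of divergent lncRNA loci.
#' @param upstream_len upstream region length in bases (default 1000).
#' @return Named logical vector, one flag per gene.
#' @export
pair_divergent_lncrnas <- function(gs, lncrna_loci, upstream_len = 1000) {
  win <- upstream_window(gs, length = upstream_len)  # opposite strand
  hits <- GenomicRanges::findOverlaps(win, lncrna_loci,
                                      ignore.strand = FALSE)
  out <- stats::setNames(logical(length(win)), names(win))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}

#' Mutually exclusive chromatin classes from promoter marks
#'
#' Partitions genes into H3K4me3-only, H3K27me3-only, bivalent and neither,
#' from promoter overlap flags.
#'
#' @param k4,k27 logical vectors: promoter overlaps H3K4me3 / H3K27me3.
#' @return Factor with levels `h3k4me3_only`, `h3k27me3_only`, `bivalent`,
#'   `neither`.
#' @export
chromatin_class <- function(k4, k27) {
  factor(ifelse(k4 & k27, "bivalent",
                ifelse(k4, "h3k4me3_only",
                       ifelse(k27, "h3k27me3_only", "neither"))),
         levels = c("h3k4me3_only", "h3k27me3_only", "bivalent", "neither"))
}
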