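#' Published pipeline constants
#'
#' All thresholds the pipeline applies, with their default (published)
#' values. Every run records the values actually used, so defaults are
#' auditable.
#'
#' @return Named list of parameters.
#' @export
pipeline_defaults <- function() {
  list(
    rpkm_expressed = 5,          # mean control RPKM for "expressed" (strict)
    cpm_min = 1,                 # CPM filter for DE testing (strict)
    cpm_min_samples = 2,         # ... in at least this many samples
    de_fc_threshold = 1.5,       # linear fold change for DE calls
    de_fdr = 0.05,               # BH FDR (strict)
    pseudocount = 1,             # added to normalized counts for FCs
    bg_offsets = c(1, 3, 5, 7, 9) * 1000,  # background window offsets
    bg_width = 2000,             # background window width
    udrna_upstream = 5000,       # udRNA search window
    udrna_min_count = 10,        # udRNA normalized-count floor
    udrna_bg_factor = 2,         # udRNA fold over background
    udrna_regulated_fold = 2,    # udRNA "repressed" fold change
    divergent_gap = 10000,       # divergent close-pair exclusion (TSS-TSS)
    body_bins = 100,             # gene-body bins
    flank_bins = 500,            # flank bins ...
    flank_bin = 200,             # ... of this many bases
    enrich_min_density = 0.005,  # enrichment-region density cutoff
    enrich_window = 10,          # ... within this sliding window (bins)
    rt_fc_threshold = 1.5,       # readthrough fold change (linear)
    rt_min_potential = 1000,     # downstream region size, potential (excl.)
    rt_min_candidate = 3000,     # downstream region size, candidate (excl.)
    rt_lookback = 100000,        # upstream initiating-locus search
    extent_scan = 1e6,           # extent scan window from the PAS
    extent_min_density = 0.01,   # segment-merge density (strict >)
    promoter_up = 5000,          # promoter: upstream of TSS
    promoter_down = 1000,        # promoter: downstream of TSS
    min_overlap = 1,             # feature overlap, bases
    overlap_min_gene_length = 1000,  # overlap universe gene length (excl.)
    lncrna_upstream = 1000)      # divergent lncRNA pairing window
}

count_stage <- function(gs, read_sets, design, params) {
  counts <- sapply(read_sets[design$sample_id], function(rs)
    count_gene_reads(rs, gs))
  total_mapped <- vapply(read_sets[design$sample_id], function(rs)
    rs$total_mapped, numeric(1))
  ct <- count_table(counts, total_mapped)
  rpkm <- sweep(sweep(counts, 1, gs$genes$exonic_length / 1000, `/`),
                2, ct$lib_sizes / 1e6, `/`)
  ctrl <- design$sample_id[design$aso == "scrambled"]
  expressed <- is_expressed(rpkm[, ctrl, drop = FALSE],
                            threshold = params$rpkm_expressed)
  list(ct = ct, rpkm = rpkm, expressed = expressed)
}

termination_stage <- function(gs, read_sets, design, nf, expressed, params) {
  ids <- gs$genes$gene_id
  samples <- design$sample_id
  scales <- stats::setNames(norm_scale(nf, samples), samples)
  region_rows <- vector("list", length(ids))
  region_counts <- matrix(0, length(ids), length(samples),
                          dimnames = list(ids, samples))
  down_dens <- list()
  pools <- lapply(read_sets[samples], read_pool)
  for (i in seq_along(ids)) {
    id <- ids[i]
    per_sample <- lapply(samples, function(s)
      bin_gene_and_flanks(gs, id, pools[[s]], scale = scales[[s]],
                          body_bins = params$body_bins,
                          flank_bins = params$flank_bins,
                          flank_bin = params$flank_bin))
    if (is.null(per_sample[[1]])) next
    down <- sapply(per_sample, function(x) x$downstream$density)
    if (length(down) == 0) next
    down <- as.matrix(down)
    down_dens[[id]] <- down
    pooled <- rowMeans(down)
    regs <- find_enrichment_regions(pooled,
                                    min_density = params$enrich_min_density,
                                    window = params$enrich_window)
    regs <- regs[regs$start_bin == 1, , drop = FALSE]  # abutting the PAS
    if (nrow(regs) == 0) next
    nb <- regs$n_bins[1]
    cm <- matrix(unlist(lapply(per_sample, function(x)
      x$downstream$counts[seq_len(nb)])), nrow = nb)
    cnt <- stats::setNames(colSums(cm), samples)
    region_counts[i, ] <- cnt
    fc <- region_log2fc(cnt, design)
    region_rows[[i]] <- data.frame(gene_id = id,
                                   size = nb * params$flank_bin,
                                   n_bins = nb,
                                   fc_5p = fc[["anti_7sk_5p"]],
                                   fc_3p = fc[["anti_7sk_3p"]],
                                   stringsAsFactors = FALSE)
  }
  found <- !vapply(region_rows, is.null, logical(1))
  region_tbl <- data.frame(gene_id = ids, size = 0, n_bins = 0,
                           fc_5p = NA_real_, fc_3p = NA_real_,
                           stringsAsFactors = FALSE)
  if (any(found))
    region_tbl[found, ] <- do.call(rbind, region_rows[found])
  cand <- call_readthrough_candidates(
    gs, region_tbl, expressed,
    fc_threshold = params$rt_fc_threshold,
    min_potential = params$rt_min_potential,
    min_candidate = params$rt_min_candidate,
    lookback = params$rt_lookback)

  kd_samples <- design$sample_id[design$aso != "scrambled"]
  ext <- rep(NA_real_, length(ids))
  for (i in which(cand$is_candidate)) {
    g <- gs$genes[i]
    strand <- as.character(GenomicRanges::strand(g))
    chrom <- as.character(GenomicRanges::seqnames(g))
    pas <- g$pas
    cl <- if (strand == "+")
      anchored_flank("right", pas, params$extent_scan, params$flank_bin,
                     chrom, gs$chrom_sizes)
    else
      anchored_flank("left", pas, params$extent_scan, params$flank_bin,
                     chrom, gs$chrom_sizes)
    if (is.null(cl)) { ext[i] <- 0; next }
    iv <- GenomicRanges::GRanges(chrom, IRanges::IRanges(cl$start, cl$end))
    dens <- sapply(kd_samples, function(s)
      bin_density(pools[[s]], iv, strand,
                  bin_size = params$flank_bin,
                  scale = scales[[s]])$density)
    v <- rowMeans(as.matrix(dens))
    if (strand == "-") v <- rev(v)
    ext[i] <- estimate_readthrough_extent(
      v, bin_size = params$flank_bin,
      min_segment_density = params$extent_min_density)$extent
  }
  cand$extent <- ext
  list(regions = cand, region_counts = region_counts,
       downstream_density = down_dens)
}

#' Run the full analysis pipeline
#'
#' Orchestrates counting, normalization, differential expression (raw and
#' background-adjusted), udRNA detection, readthrough detection with
#' extent estimation, and optional feature-overlap enrichment, on gene
#' models plus stranded read sets. Optionally writes result tables (TSV),
#' called regions (BED6) and a JSON run log recording every threshold
#' used.
#'
#' @param gs a `GeneSet`.
#' @param read_sets named list of `StrandedReadSet`s covering the design.
#' @param design a `SampleDesign`.
#' @param outdir optional output directory.
#' @param norm_method `"tmm"` (default) or `"total_count"`; all region
#'   thresholds consume counts normalized with the gene-derived factors of
#'   the chosen method.
#' @param features optional named list of `GRanges` feature sets for the
#'   enrichment stage.
#' @param params pipeline constants, see [pipeline_defaults()].
#' @param stages subset of
#'   `c("count","normalize","de","adjust","udrna","termination","enrich")`.
#' @return Named list with the per-stage result tables.
#' @export
run_pipeline <- function(gs, read_sets, design, outdir = NULL,
                         norm_method = c("tmm", "total_count"),
                         features = NULL, params = pipeline_defaults(),
                         stages = c("count", "normalize", "de", "adjust",
                                    "udrna", "termination", "enrich")) {
  norm_method <- match.arg(norm_method)
  missing_rs <- setdiff(design$sample_id, names(read_sets))
  if (length(missing_rs))
    stop("read sets missing for sample(s): ",
         paste(missing_rs, collapse = ", "))
  need <- function(stage, deps) {
    bad <- setdiff(deps, stages)
    if (length(bad)) stop("stage '", stage, "' requires stage(s): ",
                          paste(bad, collapse = ", "))
  }
  out <- list(params = params, norm_method = norm_method)

  if ("count" %in% stages) {
    cs <- count_stage(gs, read_sets, design, params)
    out$counts <- cs$ct
    out$rpkm <- cs$rpkm
    out$expressed <- cs$expressed
  }
  if ("normalize" %in% stages) {
    need("normalize", "count")
    out$nf <- if (norm_method == "tmm") tmm_factors(out$counts)
              else total_count_factors(out$counts)
  }
  if ("de" %in% stages) {
    need("de", c("count", "normalize"))
    out$de <- run_differential_expression(
      out$counts, design, out$nf,
      fc_threshold = params$de_fc_threshold, fdr = params$de_fdr,
      cpm_min = params$cpm_min, min_samples = params$cpm_min_samples)
  }
  if ("adjust" %in% stages) {
    need("adjust", c("count", "normalize"))
    out$adjusted <- adjusted_count_matrix(gs, out$counts, read_sets, out$nf)
    out$de_adjusted <- run_differential_expression(
      out$counts, design, out$nf, adjusted_counts = out$adjusted,
      fc_threshold = params$de_fc_threshold, fdr = params$de_fdr,
      cpm_min = params$cpm_min, min_samples = params$cpm_min_samples)
  }
  if ("udrna" %in% stages) {
    need("udrna", c("count", "normalize"))
    ctrl <- design$sample_id[design$aso == "scrambled"]
    kd3 <- design$sample_id[design$aso == "anti_7sk_3p"]
    kd_all <- design$sample_id[design$aso != "scrambled"]
    calls <- detect_udrnas(gs, read_sets[ctrl], read_sets[kd3], out$nf,
                           upstream_len = params$udrna_upstream,
                           min_count = params$udrna_min_count,
                           bg_factor = params$udrna_bg_factor,
                           min_gap = params$divergent_gap)
    out$udrna <- quantify_udrna_response(
      calls, read_sets[kd_all], read_sets[ctrl], out$nf,
      pseudocount = params$pseudocount,
      regulated_fold = params$udrna_regulated_fold)
  }
  if ("termination" %in% stages) {
    need("termination", c("count", "normalize"))
    expressed <- stats::setNames(out$expressed, gs$genes$gene_id)
    out$termination <- termination_stage(gs, read_sets, design, out$nf,
                                         expressed, params)
  }
  if ("enrich" %in% stages && !is.null(features)) {
    need("enrich", "count")
    uni <- overlap_universe(gs, params$overlap_min_gene_length)
    prom <- promoter_region(gs, up = params$promoter_up,
                            down = params$promoter_down, gene_ids = uni)
    flags <- sapply(features, function(f)
      overlap_features(prom, f, min_overlap = params$min_overlap))
    flags <- matrix(flags, nrow = length(uni),
                    dimnames = list(uni, names(features)))
    out$enrich <- list(universe = uni,
                       promoter_flags = flags,
                       gene_density = gene_density(
                         gs, window = params$rt_lookback,
                         min_length = params$overlap_min_gene_length))
  }
  if (!is.null(outdir)) write_pipeline_outputs(out, gs, design, outdir)
  out
}

write_pipeline_outputs <- function(out, gs, design, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) write.table(
    df, file.path(outdir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (!is.null(out$counts)) {
    expr <- data.frame(gene_id = rownames(out$counts$counts),
                       out$counts$counts, check.names = FALSE)
    expr$mean_ctrl_rpkm <- rowMeans(
      out$rpkm[, design$sample_id[design$aso == "scrambled"], drop = FALSE])
    expr$expressed <- out$expressed
    tsv(expr, "gene_expression.tsv")
  }
  if (!is.null(out$de)) tsv(out$de$consensus, "de_consensus.tsv")
  if (!is.null(out$de_adjusted))
    tsv(out$de_adjusted$consensus, "de_adjusted_consensus.tsv")
  if (!is.null(out$udrna)) {
    tsv(as.data.frame(out$udrna), "udrna_calls.tsv")
    if (nrow(out$udrna) > 0) {
      bed <- data.frame(out$udrna$chrom, out$udrna$start - 1L,
                        out$udrna$end, out$udrna$gene_id, 0L,
                        out$udrna$strand)
      write.table(bed, file.path(outdir, "udrna_calls.bed"), sep = "\t",
                  quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
  }
  if (!is.null(out$termination)) tsv(out$termination$regions,
                                     "readthrough_regions.tsv")
  log <- list(parameters = out$params, norm_method = out$norm_method,
              samples = design$sample_id,
              package_version = as.character(utils::packageVersion("readthroughr")))
  writeLines(jsonlite::toJSON(log, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(outdir, "run_log.json"))
  invisible(outdir)
}
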