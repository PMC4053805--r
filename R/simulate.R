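#' Simulation configuration
#'
#' Defaults describe the reference synthetic dataset: 200 non-overlapping
#' stranded genes on 2 chromosomes, a 2+2+2 design (scrambled, 5' ASO,
#' 3' ASO, with one sample of each in each of two batches), negative
#' binomial replicate noise at dispersion 0.1, uniform low background on
#' both strands, and planted effect classes — direct 4x targets, udRNAs at
#' several-fold over background, isolated readthrough genes with extents of
#' 4-40 kb, passenger genes seated inside the readthrough region of a
#' dedicated host gene, readthrough-across-promoter confounders, and
#' closely spaced divergent gene pairs.
#'
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the configuration including the seed.
#' @param ... overrides for any default listed below.
#' @return List of class `SimulationConfig`.
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_chroms = 2,
    chrom_length = 7e6,
    potential_spacing = 105000,  # keep unrelated readthrough loci apart
                                 # (beyond the 100 kb initiating-locus
                                 # lookback), so planted chains are the
                                 # only chains
    read_length = 50,
    dispersion = 0.1,
    background_density = 5e-4,      # reads per base per strand, all samples
    # design: sample depth multipliers; suffix _1/_2 marks the batch
    depth = c(scr_1 = 1.00, scr_2 = 0.92, a5_1 = 1.08, a5_2 = 0.96,
              a3_1 = 1.04, a3_2 = 1.12),
    # gene architecture
    gene_length_range = c(2000, 8000),
    n_exons_range = c(2, 8),
    gap_range = c(15000, 30000),
    expr_density_range = c(0.03, 0.10),  # exonic reads per base (control)
    intron_density_frac = 0.1,
    silent_density = 0.0015,
    n_null = 30, n_null_silent = 10, n_null_lincrna = 10,
    # planted effects
    n_direct = 30, direct_fold = 4,
    n_udrna = 50, udrna_density = 0.004, udrna_fold = 3, udrna_len = 5000,
    n_readthrough = 20, rt_extent_range = c(4000, 40000),
    rt_density_start = 0.05, rt_density_end = 0.015, rt_block = 2000,
    n_passenger = 20, passenger_gap = 12000, host_overhang = 5000,
    host_density_start = 0.08, host_density_end = 0.04,
    passenger_density_range = c(0.02, 0.05),
    n_confounder = 10, confounder_offset = 13000,
    confounder_overhang = 7000,
    conf_density_start = 0.06, conf_density_end = 0.03,
    n_divergent_pairs = 5, divergent_tss_gap = 6000)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg$n_genes <- cfg$n_null + cfg$n_direct + cfg$n_udrna +
    cfg$n_readthrough + 2 * cfg$n_passenger + 2 * cfg$n_confounder +
    2 * cfg$n_divergent_pairs
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Reference sample design
#'
#' Two scrambled-control samples and two biological replicates per
#' knockdown ASO, one per batch.
#'
#' @return A `SampleDesign`.
#' @export
default_design <- function() {
  sample_design(
    sample_id = c("scr_1", "scr_2", "a5_1", "a5_2", "a3_1", "a3_2"),
    aso = c("scrambled", "scrambled", "anti_7sk_5p", "anti_7sk_5p",
            "anti_7sk_3p", "anti_7sk_3p"),
    batch = c(1, 2, 1, 2, 1, 2))
}

runif_int <- function(n, range) {
  floor(stats::runif(n, range[1], range[2] + 1))
}

# partition a gene of length L into k exons separated by k-1 introns;
# returns a 2-column matrix of exon [start, end] relative to 1..L
make_exon_layout <- function(L, k) {
  k <- max(1, min(k, floor(L / 160)))
  m <- 2 * k - 1
  u <- stats::runif(m, 0.6, 1.4)
  w <- floor(u / sum(u) * L)
  w[m] <- L - sum(w[-m])
  e <- cumsum(w)
  s <- e - w + 1
  idx <- seq(1, m, by = 2)
  cbind(s[idx], e[idx])
}

rt_blocks <- function(extent, d_start, d_end, block) {
  nb <- ceiling(extent / block)
  widths <- rep(block, nb)
  if (extent %% block) widths[nb] <- extent %% block
  r <- if (nb > 1) (d_end / d_start)^(1 / (nb - 1)) else 1
  list(widths = widths, density = d_start * r^(seq_len(nb) - 1))
}

#' Simulate a toy annotated genome with planted effects
#'
#' Places non-overlapping stranded multi-exon genes along the chromosomes
#' with per-class geometric constraints (readthrough regions get clear
#' downstream space; passengers sit inside their host's readthrough region
#' with their background windows fully covered; confounder sources are
#' placed so their readthrough sweeps across the victim's promoter on the
#' antisense strand; divergent pairs sit head-to-head within the exclusion
#' distance). Deterministic under the config seed.
#'
#' @param cfg a `SimulationConfig`.
#' @return List with `genes` (a `GeneSet`) and `truth` (a
#'   `SimulationTruth` data.frame).
#' @export
simulate_annotation <- function(cfg) {
  set.seed(cfg$seed)
  units <- c(rep("direct", cfg$n_direct),
             rep("udrna", cfg$n_udrna),
             rep("null", cfg$n_null),
             rep("readthrough", cfg$n_readthrough),
             rep("passenger_pair", cfg$n_passenger),
             rep("confounder_pair", cfg$n_confounder),
             rep("divergent_pair", cfg$n_divergent_pairs))
  units <- sample(units)
  chrom_of <- rep_len(seq_len(cfg$n_chroms), length(units))  # round robin

  null_flavor <- sample(c(rep("silent", cfg$n_null_silent),
                          rep("lincrna", cfg$n_null_lincrna),
                          rep("plain", cfg$n_null - cfg$n_null_silent -
                                cfg$n_null_lincrna)))
  null_i <- 0

  rows <- list(); exon_list <- list(); gi <- 0
  cursor <- stats::setNames(rep(15000, cfg$n_chroms),
                            paste0("chr", seq_len(cfg$n_chroms)))

  add_gene <- function(chrom, start, L, strand, biotype, class, density,
                       expressed, extras = list()) {
    gi <<- gi + 1
    id <- sprintf("g%03d", gi)
    ex <- make_exon_layout(L, runif_int(1, cfg$n_exons_range))
    exon_list[[id]] <<- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(start + ex[, 1] - 1, start + ex[, 2] - 1),
      strand = strand)
    row <- list(gene_id = id, chrom = chrom, start = start,
                end = start + L - 1, strand = strand, biotype = biotype,
                class = class, expr_density = density,
                expressed = expressed,
                direct = FALSE, direct_fold = 1,
                udrna = FALSE, udrna_start = NA_integer_,
                udrna_end = NA_integer_, udrna_fold = 1,
                readthrough = FALSE, rt_extent = NA_integer_,
                rt_density_start = NA_real_, rt_density_end = NA_real_,
                passenger = FALSE, host_id = NA_character_,
                confounder_victim = FALSE, source_id = NA_character_)
    row[names(extras)] <- extras
    rows[[gi]] <<- row
    id
  }
  gene_len <- function() runif_int(1, cfg$gene_length_range)
  expr_density <- function() stats::runif(1, cfg$expr_density_range[1],
                                          cfg$expr_density_range[2])
  base_gap <- function() runif_int(1, cfg$gap_range)

  last_pot <- stats::setNames(rep(-Inf, cfg$n_chroms),
                              paste0("chr", seq_len(cfg$n_chroms)))
  for (u in seq_along(units)) {
    type <- units[u]
    ch <- paste0("chr", chrom_of[u])
    gi_before <- gi
    if (type %in% c("readthrough", "passenger_pair", "confounder_pair"))
      cursor[ch] <- max(cursor[ch], last_pot[ch] + cfg$potential_spacing)
    o <- cursor[ch]
    strand <- sample(c("+", "-"), 1)
    if (type %in% c("direct", "udrna", "null")) {
      L <- gene_len()
      flavor <- "plain"
      if (type == "null") { null_i <- null_i + 1; flavor <- null_flavor[null_i] }
      d <- if (flavor == "silent") cfg$silent_density else expr_density()
      biotype <- if (flavor == "lincrna") "lincRNA" else "protein_coding"
      extras <- list()
      if (type == "direct") extras <- list(direct = TRUE,
                                           direct_fold = cfg$direct_fold)
      if (type == "udrna") {
        tss <- if (strand == "+") o else o + L - 1
        us <- if (strand == "+") tss - cfg$udrna_len else tss + 1
        ue <- if (strand == "+") tss - 1 else tss + cfg$udrna_len
        extras <- list(udrna = TRUE, udrna_start = us, udrna_end = ue,
                       udrna_fold = cfg$udrna_fold)
      }
      add_gene(ch, o, L, strand, biotype, type, d,
               expressed = flavor != "silent", extras)
      cursor[ch] <- o + L + base_gap()
    } else if (type == "readthrough") {
      e <- 200 * round(stats::runif(1, cfg$rt_extent_range[1],
                                    cfg$rt_extent_range[2]) / 200)
      L <- gene_len()
      if (strand == "-") o <- o + e + 13000  # leave room for the region
      add_gene(ch, o, L, strand, "protein_coding", "readthrough",
               expr_density(), TRUE,
               list(readthrough = TRUE, rt_extent = e,
                    rt_density_start = cfg$rt_density_start,
                    rt_density_end = cfg$rt_density_end))
      right <- o + L - 1 + if (strand == "+") e + 13000 else 0
      cursor[ch] <- max(right, o + L - 1) + base_gap()
    } else if (type == "passenger_pair") {
      Lh <- gene_len(); Lp <- runif_int(1, c(2000, 4000))
      gap_p <- cfg$passenger_gap
      e <- gap_p + Lp + cfg$host_overhang
      dpass <- stats::runif(1, cfg$passenger_density_range[1],
                            cfg$passenger_density_range[2])
      host_extras <- list(readthrough = TRUE, rt_extent = e,
                          rt_density_start = cfg$host_density_start,
                          rt_density_end = cfg$host_density_end)
      if (strand == "+") {
        hid <- add_gene(ch, o, Lh, "+", "protein_coding", "host",
                        expr_density(), TRUE, host_extras)
        ps <- o + Lh - 1 + gap_p + 1
        add_gene(ch, ps, Lp, "+", "protein_coding", "passenger", dpass,
                 TRUE, list(passenger = TRUE, host_id = hid))
        cursor[ch] <- o + Lh - 1 + e + 13000 + base_gap()
      } else {
        o <- o + cfg$host_overhang + 12000  # region reaches left of the unit
        add_gene(ch, o, Lp, "-", "protein_coding", "passenger", dpass,
                 TRUE, list(passenger = TRUE, host_id = sprintf("g%03d", gi + 2)))
        hs <- o + Lp - 1 + gap_p + 1
        hid <- add_gene(ch, hs, Lh, "-", "protein_coding", "host",
                        expr_density(), TRUE, host_extras)
        rows[[gi - 1]]$host_id <- hid
        cursor[ch] <- hs + Lh - 1 + base_gap()
      }
    } else if (type == "confounder_pair") {
      Lb <- gene_len(); Lc <- runif_int(1, c(3000, 6000))
      off <- cfg$confounder_offset
      e <- off + cfg$udrna_len + 2000
      conf_extras <- list(readthrough = TRUE, rt_extent = e,
                          rt_density_start = cfg$conf_density_start,
                          rt_density_end = cfg$conf_density_end)
      if (strand == "+") {
        # victim (+) first, source (-) to its right; readthrough sweeps left
        o <- o + cfg$confounder_overhang + 12000
        vid <- add_gene(ch, o, Lb, "+", "protein_coding",
                        "confounder_victim", expr_density(), TRUE,
                        list(confounder_victim = TRUE,
                             source_id = sprintf("g%03d", gi + 2)))
        cs <- o + off
        sid <- add_gene(ch, cs, Lc, "-", "protein_coding",
                        "confounder_source", expr_density(), TRUE,
                        conf_extras)
        rows[[gi - 1]]$source_id <- sid
        cursor[ch] <- cs + Lc - 1 + base_gap()
      } else {
        # source (+) first, victim (-) to its right; readthrough sweeps right
        sid <- add_gene(ch, o, Lc, "+", "protein_coding",
                        "confounder_source", expr_density(), TRUE,
                        conf_extras)
        vtss <- o + Lc - 1 + off
        vs <- vtss - Lb + 1
        add_gene(ch, vs, Lb, "-", "protein_coding", "confounder_victim",
                 expr_density(), TRUE,
                 list(confounder_victim = TRUE, source_id = sid))
        cursor[ch] <- vtss + cfg$confounder_overhang + 12000 + base_gap()
      }
    } else if (type == "divergent_pair") {
      Lm <- gene_len(); Lp <- gene_len()
      # minus gene then plus gene, head-to-head TSSs within the exclusion gap
      add_gene(ch, o, Lm, "-", "protein_coding", "divergent_pair",
               expr_density(), TRUE)
      ps <- o + Lm - 1 + cfg$divergent_tss_gap
      add_gene(ch, ps, Lp, "+", "protein_coding", "divergent_pair",
               expr_density(), TRUE)
      cursor[ch] <- ps + Lp - 1 + base_gap()
    }
    if (type %in% c("readthrough", "passenger_pair", "confounder_pair"))
      last_pot[ch] <- max(vapply(rows[(gi_before + 1):gi],
                                 function(r) r$end, numeric(1)))
  }
  if (any(cursor > cfg$chrom_length - 1.1e6))
    stop("chromosome too short for the configured genes; increase ",
         "chrom_length (need > ", max(cursor) + 1.1e6, ")")

  truth <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  class(truth) <- c("SimulationTruth", "data.frame")

  genes <- GenomicRanges::GRanges(truth$chrom,
                                  IRanges::IRanges(truth$start, truth$end),
                                  strand = truth$strand)
  genes$gene_id <- truth$gene_id
  genes$biotype <- truth$biotype
  plus <- truth$strand == "+"
  genes$tss <- ifelse(plus, truth$start, truth$end)
  genes$final_tss <- genes$tss  # single-isoform simulation
  genes$pas <- ifelse(plus, truth$end, truth$start)
  genes$exonic_length <- unname(vapply(exon_list[truth$gene_id],
                                       function(x)
                                         sum(GenomicRanges::width(x)),
                                       numeric(1)))
  chrom_sizes <- stats::setNames(rep(cfg$chrom_length, cfg$n_chroms),
                                 paste0("chr", seq_len(cfg$n_chroms)))
  gs <- gene_set(genes, methods::as(exon_list, "GRangesList"), chrom_sizes)
  truth <- truth[match(gs$genes$gene_id, truth$gene_id), ]
  rownames(truth) <- NULL
  list(genes = gs, truth = truth)
}

# planted region table: one row per (group, region) with per-class strand
# and control/knockdown densities
planted_regions <- function(cfg, gs, truth) {
  out <- list()
  add <- function(group, chrom, start, end, strand, d_ctrl, d_kd) {
    out[[length(out) + 1]] <<- data.frame(
      group = group, chrom = chrom, start = start, end = end,
      strand = strand, d_ctrl = d_ctrl, d_kd = d_kd,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    ex <- gs$exons[[tr$gene_id]]
    fold <- if (tr$direct) tr$direct_fold else 1
    for (j in seq_along(ex))
      add(paste0(tr$gene_id, ".expr"), tr$chrom,
          GenomicRanges::start(ex)[j], GenomicRanges::end(ex)[j],
          tr$strand, tr$expr_density, tr$expr_density * fold)
    body_iv <- GenomicRanges::GRanges(tr$chrom,
                                      IRanges::IRanges(tr$start, tr$end))
    al <- align_seqlevels(body_iv, GenomicRanges::granges(ex))
    intr <- GenomicRanges::setdiff(al$a, al$b, ignore.strand = TRUE)
    di <- tr$expr_density * cfg$intron_density_frac
    for (j in seq_along(intr))
      add(paste0(tr$gene_id, ".expr"), tr$chrom,
          GenomicRanges::start(intr)[j], GenomicRanges::end(intr)[j],
          tr$strand, di, di * fold)
    if (tr$udrna) {
      anti <- if (tr$strand == "+") "-" else "+"
      add(paste0(tr$gene_id, ".ud"), tr$chrom, tr$udrna_start, tr$udrna_end,
          anti, cfg$udrna_density, cfg$udrna_density * tr$udrna_fold)
    }
    if (tr$readthrough) {
      bl <- rt_blocks(tr$rt_extent, tr$rt_density_start, tr$rt_density_end,
                      cfg$rt_block)
      pas <- if (tr$strand == "+") tr$end else tr$start
      pos <- pas
      for (k in seq_along(bl$widths)) {
        w <- bl$widths[k]
        if (tr$strand == "+") { s <- pos + 1; e <- pos + w; pos <- e }
        else { e <- pos - 1; s <- pos - w; pos <- s }
        add(paste0(tr$gene_id, ".rt"), tr$chrom, s, e, tr$strand,
            0, bl$density[k])
      }
    }
  }
  for (ch in names(gs$chrom_sizes)) for (s in c("+", "-"))
    add(paste0("bg.", ch, s), ch, 1, gs$chrom_sizes[[ch]], s,
        cfg$background_density, cfg$background_density)
  do.call(rbind, out)
}

#' Simulate stranded read sets
#'
#' Realizes per-region read counts as negative binomial (a shared
#' per-(group, sample) gamma multiplier at the configured dispersion times
#' Poisson draws per region, so gene-level counts are NB at the configured
#' dispersion) and places fixed-length reads uniformly within each region.
#' Direct targets gain exonic and intronic reads in knockdown samples;
#' readthrough regions exist only in knockdown samples, with density
#' decaying geometrically per block away from the PAS; udRNA regions are
#' antisense and multiplied in knockdown samples; background covers both
#' strands everywhere.
#'
#' @param cfg a `SimulationConfig`.
#' @param ann result of [simulate_annotation()].
#' @param design a `SampleDesign` whose sample ids match `cfg$depth`.
#' @return Named list of `StrandedReadSet`s.
#' @export
simulate_reads <- function(cfg, ann, design = default_design()) {
  set.seed(cfg$seed + 1L)
  stopifnot(all(design$sample_id %in% names(cfg$depth)))
  reg <- planted_regions(cfg, ann$genes, ann$truth)
  reg$width <- reg$end - reg$start + 1
  groups <- unique(reg$group)
  shape <- 1 / cfg$dispersion
  rl <- cfg$read_length
  out <- list()
  for (s in design$sample_id) {
    kd <- design$aso[design$sample_id == s] != "scrambled"
    depth <- cfg$depth[[s]]
    dens <- if (kd) reg$d_kd else reg$d_ctrl
    starts_all <- integer(0); chroms_all <- character(0)
    strands_all <- character(0)
    for (g in groups) {
      idx <- which(reg$group == g)
      lambda <- stats::rgamma(1, shape = shape, scale = 1 / shape)
      mu <- dens[idx] * reg$width[idx] * depth * lambda
      n <- stats::rpois(length(idx), mu)
      tot <- sum(n)
      if (tot == 0) next
      ii <- rep(idx, n)
      p <- floor(stats::runif(tot, reg$start[ii] - (rl / 2 - 1),
                              reg$end[ii] - rl / 2 + 1))
      starts_all <- c(starts_all, p)
      chroms_all <- c(chroms_all, reg$chrom[ii])
      strands_all <- c(strands_all, reg$strand[ii])
    }
    starts_all <- pmax(starts_all, 1)
    gr <- GenomicRanges::GRanges(chroms_all,
                                 IRanges::IRanges(starts_all,
                                                  starts_all + rl - 1),
                                 strand = strands_all)
    lim <- ann$genes$chrom_sizes[as.character(GenomicRanges::seqnames(gr))]
    GenomicRanges::end(gr) <- pmin(GenomicRanges::end(gr), lim)
    ord <- order(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr),
                 as.character(GenomicRanges::strand(gr)))
    out[[s]] <- stranded_read_set(gr[ord], s)
  }
  out
}

#' Simulate a complete dataset
#'
#' Annotation, truth table and one read set per sample; optionally written
#' to disk as GTF, BED6, TSV (chromosome sizes, design, truth).
#'
#' @param cfg a `SimulationConfig`.
#' @param dir optional output directory.
#' @param design a `SampleDesign`.
#' @return List with `genes`, `truth`, `read_sets`, `design`, and `paths`
#'   (when written).
#' @export
simulate_dataset <- function(cfg = sim_config(), dir = NULL,
                             design = default_design()) {
  ann <- simulate_annotation(cfg)
  read_sets <- simulate_reads(cfg, ann, design)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      gtf = file.path(dir, "annotation.gtf"),
      truth = file.path(dir, "truth.tsv"),
      chrom_sizes = file.path(dir, "chrom_sizes.tsv"),
      design = file.path(dir, "design.tsv"),
      reads = stats::setNames(
        file.path(dir, paste0("reads_", design$sample_id, ".bed")),
        design$sample_id))
    write_gtf(ann$genes, paths$gtf)
    write_truth(ann$truth, paths$truth)
    write.table(data.frame(chrom = names(ann$genes$chrom_sizes),
                           length = unname(ann$genes$chrom_sizes)),
                paths$chrom_sizes, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    write.table(design, paths$design, sep = "\t", quote = FALSE,
                row.names = FALSE)
    for (s in design$sample_id) write_reads_bed(read_sets[[s]],
                                                paths$reads[[s]])
  }
  c(ann, list(read_sets = read_sets, design = design, paths = paths))
}

#' Write a GeneSet as GTF
#'
#' One exon feature per merged exon, Ensembl attribute dialect.
#'
#' @param gs a `GeneSet`.
#' @param path output path.
#' @export
write_gtf <- function(gs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in gs$genes$gene_id) {
    ex <- gs$exons[[id]]
    bt <- gs$genes$biotype[match(id, gs$genes$gene_id)]
    if (length(ex) == 0) next
    lines <- sprintf(
      '%s\tsim\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s.t1"; gene_biotype "%s";',
      as.character(GenomicRanges::seqnames(ex)), GenomicRanges::start(ex),
      GenomicRanges::end(ex), as.character(GenomicRanges::strand(ex)),
      id, id, bt)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write reads as BED6
#'
#' @param rs a `StrandedReadSet`.
#' @param path output path.
#' @export
write_reads_bed <- function(rs, path) {
  gr <- rs$reads
  df <- data.frame(as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
                   paste0("r", seq_along(gr)), 0L,
                   as.character(GenomicRanges::strand(gr)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write and read the planted-effect truth table
#'
#' @param truth a `SimulationTruth` data.frame.
#' @param path TSV path.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tr <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  tr$host_id <- as.character(tr$host_id)
  tr$source_id <- as.character(tr$source_id)
  class(tr) <- c("SimulationTruth", "data.frame")
  tr
}
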