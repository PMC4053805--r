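#' Sample design tables
#'
#' @param sample_id sample identifiers.
#' @param aso one of `"scrambled"`, `"anti_7sk_5p"`, `"anti_7sk_3p"` per
#'   sample.
#' @param batch experiment batch (1 or 2) per sample.
#' @return data.frame of class `SampleDesign`.
#' @export
sample_design <- function(sample_id, aso, batch) {
  aso <- match.arg(aso, c("scrambled", "anti_7sk_5p", "anti_7sk_3p"),
                   several.ok = TRUE)
  d <- data.frame(sample_id = sample_id, aso = aso, batch = as.integer(batch),
                  stringsAsFactors = FALSE)
  class(d) <- c("SampleDesign", "data.frame")
  d
}

#' Minimal-expression filter
#'
#' Retains genes with counts per million exonic reads (CPM) strictly above
#' `cpm_min` in at least `min_samples` of the tested samples.
#'
#' @param ct a `CountTable` (library sizes = per-sample exonic totals).
#' @param cpm_min CPM threshold (default 1).
#' @param min_samples minimum number of samples above threshold (default 2).
#' @return Character vector of retained feature ids.
#' @export
expression_filter <- function(ct, cpm_min = 1, min_samples = 2) {
  cpm <- sweep(ct$counts, 2, ct$lib_sizes / 1e6, `/`)
  keep <- rowSums(cpm > cpm_min) >= min_samples
  rownames(ct$counts)[keep]
}

#' Negative-binomial dispersion estimation
#'
#' Estimates common, trended and gene-wise dispersions with empirical-Bayes
#' shrinkage toward the common value (edgeR's `estimateDisp`). Dispersions
#' are floored at 1e-6.
#'
#' @param counts numeric matrix of counts (genes x samples).
#' @param design model matrix.
#' @param lib_sizes optional library sizes.
#' @return List with `common` and per-gene `tagwise` dispersions.
#' @export
estimate_dispersion <- function(counts, design, lib_sizes = NULL) {
  if (nrow(design) - ncol(design) < 1)
    warning("no residual degree of freedom; using common dispersion only")
  d <- edgeR::DGEList(counts = counts,
                      lib.size = lib_sizes %||% colSums(counts))
  d <- edgeR::estimateDisp(d, design)
  list(common = max(d$common.dispersion, 1e-6),
       tagwise = pmax(d$tagwise.dispersion, 1e-6))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-ASO negative-binomial GLM test
#'
#' Fits, per gene, a negative-binomial log-linear model with intercept,
#' batch and ASO terms on the samples of one knockdown ASO plus the
#' scrambled controls, and performs a likelihood-ratio test of the ASO
#' coefficient (edgeR `glmFit`/`glmLRT`). Fold changes are reported from
#' normalized means with a pseudocount of 1, separately from the model
#' coefficient; the pseudocount never enters the likelihood.
#'
#' @param ct a `CountTable`.
#' @param design a `SampleDesign` covering the columns of `ct`.
#' @param contrast_aso the knockdown ASO tested against `"scrambled"`.
#' @param nf optional `NormalizationFactors`; defaults to TMM on `ct`.
#' @param pseudocount pseudocount for reported fold changes (default 1).
#' @return data.frame: `gene_id`, `log2fc` (pseudocounted, normalized),
#'   `coef_log2fc` (GLM coefficient), `p`, `q` (BH-adjusted).
#' @export
nb_glm_test <- function(ct, design, contrast_aso, nf = NULL,
                        pseudocount = 1) {
  stopifnot(contrast_aso %in% c("anti_7sk_5p", "anti_7sk_3p"))
  use <- design$aso %in% c("scrambled", contrast_aso)
  d <- design[use, ]
  if (!all(d$sample_id %in% colnames(ct$counts)))
    stop("design samples missing from count table")
  counts <- ct$counts[, d$sample_id, drop = FALSE]
  if (is.null(nf)) nf <- tmm_factors(count_table(counts, ct$total_mapped[d$sample_id]))
  grp <- factor(ifelse(d$aso == "scrambled", "ctrl", "kd"),
                levels = c("ctrl", "kd"))
  mm <- stats::model.matrix(~ factor(batch) + grp, data = cbind(d, grp = grp))
  if (qr(mm)$rank < ncol(mm))
    stop("singular design matrix; collinear columns: ",
         paste(colnames(mm), collapse = ", "))
  dge <- edgeR::DGEList(counts = counts,
                        lib.size = unname(nf$effective[d$sample_id]))
  dge <- edgeR::estimateDisp(dge, mm)
  fit <- edgeR::glmFit(dge, mm)
  lrt <- edgeR::glmLRT(fit, coef = ncol(mm))
  p <- lrt$table$PValue

  norm <- normalized_counts(counts, nf)
  kd_mean <- rowMeans(norm[, d$sample_id[grp == "kd"], drop = FALSE])
  ctrl_mean <- rowMeans(norm[, d$sample_id[grp == "ctrl"], drop = FALSE])
  data.frame(gene_id = rownames(counts),
             log2fc = log2((kd_mean + pseudocount) /
                             (ctrl_mean + pseudocount)),
             coef_log2fc = lrt$table$logFC,
             p = p, q = bh_adjust(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' @param p vector of p-values in \[0, 1\].
#' @return Step-up adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Consensus differential-expression calls across ASOs
#'
#' A gene is called up (down) if both per-ASO tests give a q-value below
#' `fdr` (strict) and a same-direction fold change of at least
#' `fc_threshold` (linear scale, inclusive). Intersecting the two
#' independent ASO analyses conservatively rules out off-target effects.
#'
#' @param res_5p,res_3p results of [nb_glm_test()] for the two ASOs, on the
#'   same gene universe.
#' @param fc_threshold linear fold-change threshold (default 1.5).
#' @param fdr FDR threshold (default 0.05).
#' @return data.frame with per-ASO statistics and a `call` column in
#'   `{"up", "down", "ns"}`.
#' @export
call_de_genes <- function(res_5p, res_3p, fc_threshold = 1.5, fdr = 0.05) {
  if (!identical(sort(res_5p$gene_id), sort(res_3p$gene_id)))
    stop("the two ASO tests cover different gene universes")
  res_3p <- res_3p[match(res_5p$gene_id, res_3p$gene_id), ]
  lfc <- log2(fc_threshold)
  up <- res_5p$q < fdr & res_3p$q < fdr &
    res_5p$log2fc >= lfc & res_3p$log2fc >= lfc
  down <- res_5p$q < fdr & res_3p$q < fdr &
    res_5p$log2fc <= -lfc & res_3p$log2fc <= -lfc
  data.frame(gene_id = res_5p$gene_id,
             log2fc_5p = res_5p$log2fc, q_5p = res_5p$q,
             call_5p = ifelse(res_5p$q < fdr & abs(res_5p$log2fc) >= lfc,
                              ifelse(res_5p$log2fc > 0, "up", "down"), "ns"),
             log2fc_3p = res_3p$log2fc, q_3p = res_3p$q,
             call_3p = ifelse(res_3p$q < fdr & abs(res_3p$log2fc) >= lfc,
                              ifelse(res_3p$log2fc > 0, "up", "down"), "ns"),
             call = ifelse(up, "up", ifelse(down, "down", "ns")),
             stringsAsFactors = FALSE)
}

#' Differential expression with per-ASO intersection
#'
#' Runs the expression filter, the two per-ASO NB GLM tests and the
#' consensus call on a gene count table. With `adjusted = TRUE` the tests
#' run on background-adjusted normalized counts (rounded to integers, unit
#' factors), the route that controls for indirect changes caused by failed
#' termination of an upstream gene.
#'
#' @param ct a `CountTable` of gene counts.
#' @param design a `SampleDesign`.
#' @param nf a `NormalizationFactors` object (gene-derived).
#' @param adjusted_counts optional background-adjusted matrix from
#'   [adjusted_count_matrix()]; when given, testing uses these counts.
#' @param fc_threshold,fdr,cpm_min,min_samples thresholds (published
#'   defaults).
#' @return List with `per_aso` (both test tables), `consensus` (the call
#'   table) and `retained` (filtered gene ids).
#' @export
run_differential_expression <- function(ct, design, nf,
                                        adjusted_counts = NULL,
                                        fc_threshold = 1.5, fdr = 0.05,
                                        cpm_min = 1, min_samples = 2) {
  retained <- expression_filter(ct, cpm_min, min_samples)
  if (!is.null(adjusted_counts)) {
    m <- round(adjusted_counts[retained, , drop = FALSE])
    sub <- count_table(m, total_mapped = ct$total_mapped)
    nf_use <- new_norm_factors("none", colnames(m), rep(1, ncol(m)),
                               rep(mean(colSums(m)), ncol(m)),
                               effective = rep(mean(colSums(m)), ncol(m)))
  } else {
    sub <- count_table(ct$counts[retained, , drop = FALSE],
                       total_mapped = ct$total_mapped)
    sub$lib_sizes <- ct$lib_sizes  # keep full-table exonic totals
    nf_use <- nf
  }
  r5 <- nb_glm_test(sub, design, "anti_7sk_5p", nf_use)
  r3 <- nb_glm_test(sub, design, "anti_7sk_3p", nf_use)
  list(per_aso = list(anti_7sk_5p = r5, anti_7sk_3p = r3),
       consensus = call_de_genes(r5, r3, fc_threshold, fdr),
       retained = retained)
}
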