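#' Count tables
#'
#' Features x samples matrix of non-negative read counts with per-sample
#' total mapped reads. Library sizes (column sums over the counted features)
#' are used for TMM and CPM; `total_mapped` (all mapped reads) is used for
#' plain total-count scaling.
#'
#' @param counts numeric matrix, features x samples, with dimnames.
#' @param total_mapped named numeric vector of per-sample mapped totals;
#'   defaults to the column sums.
#' @return An object of class `CountTable`.
#' @export
count_table <- function(counts, total_mapped = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(colnames(counts))) stop("counts must have sample column names")
  if (is.null(names(total_mapped))) names(total_mapped) <- colnames(counts)
  if (!all(colnames(counts) %in% names(total_mapped)))
    stop("total_mapped missing for some samples")
  structure(list(counts = counts,
                 total_mapped = total_mapped[colnames(counts)],
                 lib_sizes = colSums(counts)),
            class = "CountTable")
}

#' @export
print.CountTable <- function(x, ...) {
  cat("CountTable:", nrow(x$counts), "features x", ncol(x$counts),
      "samples\n")
  invisible(x)
}

new_norm_factors <- function(method, samples, factors, lib_sizes,
                             effective) {
  # `effective` is the per-sample effective library size; normalized count
  # = raw x mean(effective) / effective
  structure(list(method = method, samples = samples,
                 factors = stats::setNames(factors, samples),
                 lib_sizes = stats::setNames(lib_sizes, samples),
                 effective = stats::setNames(effective, samples),
                 scale = stats::setNames(mean(effective) / effective,
                                         samples)),
            class = "NormalizationFactors")
}

#' @export
print.NormalizationFactors <- function(x, ...) {
  cat("NormalizationFactors (", x$method, "):\n", sep = "")
  print(round(x$factors, 4))
  invisible(x)
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values scaling factors (Robinson & Oshlack), computed
#' with edgeR: reference sample chosen by upper-quartile closeness to the
#' mean, M and A values over genes positive in both sample and reference,
#' double trimming (30% on M, 5% on A), precision-weighted mean, and factors
#' rescaled to geometric mean 1.
#'
#' @param ct a `CountTable` of gene counts. Region counts are normalized
#'   with the factors determined here for annotated genes, never fit on
#'   their own.
#' @param trim_M two-sided trim fraction on M values (default 0.30).
#' @param trim_A two-sided trim fraction on A values (default 0.05).
#' @return A `NormalizationFactors` object; `scale` holds the per-sample
#'   multiplier that takes raw to normalized counts.
#' @export
tmm_factors <- function(ct, trim_M = 0.30, trim_A = 0.05) {
  if (ncol(ct$counts) < 2) stop("TMM requires at least 2 samples")
  if (all(ct$counts == 0) ||
      !any(rowSums(ct$counts > 0) == ncol(ct$counts))) {
    warning("no gene positive in all samples; falling back to factors 1")
    f <- rep(1, ncol(ct$counts))
  } else {
    f <- edgeR::calcNormFactors(ct$counts, lib.size = ct$lib_sizes,
                                method = "TMM", logratioTrim = trim_M,
                                sumTrim = trim_A)
  }
  new_norm_factors("tmm", colnames(ct$counts), f, ct$lib_sizes,
                   effective = ct$lib_sizes * f)
}

#' Median-of-ratios normalization factors
#'
#' Size factors in the style of Anders & Huber: per sample, the median over
#' genes of the ratio of the count to the gene's geometric mean across
#' samples, rescaled to geometric mean 1.
#'
#' @param ct a `CountTable`.
#' @return A `NormalizationFactors` object.
#' @export
median_of_ratios_factors <- function(ct) {
  counts <- ct$counts
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos)) stop("no gene with positive counts in every sample")
  m <- counts[allpos, , drop = FALSE]
  gm <- exp(rowMeans(log(m)))
  sf <- apply(m / gm, 2, stats::median)
  sf <- sf / exp(mean(log(sf)))
  new_norm_factors("median_ratios", colnames(counts), sf, ct$lib_sizes,
                   effective = sf)
}

#' Total-count normalization factors
#'
#' Scales each sample so the total number of mapped reads is identical
#' across libraries: counts are divided by the per-sample mapped total and
#' multiplied by the mean mapped total.
#'
#' @param ct a `CountTable` with per-sample `total_mapped`.
#' @return A `NormalizationFactors` object.
#' @export
total_count_factors <- function(ct) {
  tm <- ct$total_mapped
  if (any(tm <= 0)) stop("total mapped reads must be positive")
  new_norm_factors("total_count", colnames(ct$counts), rep(1, length(tm)),
                   tm, effective = tm)
}

#' Total-count normalized counts
#'
#' @param ct a `CountTable`.
#' @return A `CountTable` with normalized counts.
#' @export
total_count_normalize <- function(ct) {
  nf <- total_count_factors(ct)
  out <- ct
  out$counts <- normalized_counts(ct, nf)
  out
}

#' Apply normalization factors to counts
#'
#' @param ct a `CountTable` (or plain matrix with sample columns).
#' @param nf a `NormalizationFactors` object.
#' @return Matrix of normalized counts.
#' @export
normalized_counts <- function(ct, nf) {
  m <- if (inherits(ct, "CountTable")) ct$counts else as.matrix(ct)
  sweep(m, 2, nf$scale[colnames(m)], `*`)
}

#' Per-sample normalization multiplier
#'
#' @param nf a `NormalizationFactors` object.
#' @param sample_id sample id(s).
#' @return Numeric multiplier(s) taking raw to normalized counts.
#' @export
norm_scale <- function(nf, sample_id) unname(nf$scale[sample_id])
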