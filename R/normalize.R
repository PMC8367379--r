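#' Median-of-ratios size factors
#'
#' Computes per-column size factors by the median-of-ratios method: the
#' reference for each gene is its geometric mean across all columns (genes
#' with a zero in any column are excluded from the reference set), and the
#' size factor of a column is the median over genes of count / reference.
#'
#' @param mat numeric matrix, genes x samples, non-negative.
#' @return numeric vector of size factors, one per column.
#' @examples
#' m <- cbind(a = c(10, 30, 50), b = c(20, 60, 100))
#' medianOfRatios(m)  # c(0.7071, 1.4142)
#' @export
medianOfRatios <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("counts must be non-negative")
  ok <- rowSums(mat == 0) == 0
  if (!any(ok))
    stop("normalization impossible: no gene has nonzero counts in every column")
  logGeo <- rowMeans(log(mat[ok, , drop = FALSE]))
  # median taken in log space (the ratio median of an even-sized gene set
  # is the geometric mean of the two middle ratios)
  apply(mat[ok, , drop = FALSE], 2, function(col)
    exp(median(log(col) - logGeo)))
}

#' Normalize an allele-count timecourse
#'
#' All 2T (timepoint x allele) columns of one hybrid are normalized jointly
#' by [medianOfRatios()]; normalized counts are raw counts divided by their
#' column's size factor.
#'
#' @param x an [AlleleCounts-class] object.
#' @return list with `counts` (an `AlleleCounts` carrying the normalized
#'   values) and `sizeFactors` (named per ref/alt column).
#' @export
normalizeAlleleCounts <- function(x) {
  stopifnot(is(x, "AlleleCounts"))
  wide <- cbind(refCounts(x), altCounts(x))
  colnames(wide) <- c(paste0("ref_", colnames(x)), paste0("alt_", colnames(x)))
  sf <- medianOfRatios(wide)
  T <- ncol(x)
  ref <- sweep(refCounts(x), 2, sf[seq_len(T)], "/")
  alt <- sweep(altCounts(x), 2, sf[T + seq_len(T)], "/")
  list(counts = AlleleCounts(ref, alt, timepoints = samplingTimes(x),
                             hybrid = hybridName(x)),
       sizeFactors = sf)
}

#' Filter genes on raw coverage
#'
#' A gene is removed iff its mean total (ref + alt) reads per timepoint is
#' below `minMean`, or it has more than `maxZeroTimepoints` timepoints with
#' zero total reads. Both rules apply to raw counts; boundaries are strict
#' (mean exactly `minMean` and exactly `maxZeroTimepoints` zero timepoints
#' are retained).
#'
#' @param x an [AlleleCounts-class] object.
#' @param minMean minimum mean reads per timepoint (default 20).
#' @param maxZeroTimepoints maximum tolerated zero-read timepoints
#'   (default 7).
#' @return character vector of retained gene names.
#' @export
filterGenes <- function(x, minMean = 20, maxZeroTimepoints = 7) {
  tot <- totalCounts(x)
  keep <- rowMeans(tot) >= minMean &
    rowSums(tot == 0) <= maxZeroTimepoints
  rownames(x)[keep]
}

#' Reference-allele frequency series
#'
#' For each gene, f_i = normalized ref / (normalized ref + normalized alt)
#' at timepoint i, with weights w_i equal to the raw total reads. Timepoints
#' with zero raw reads are undefined (`NA` in `f`) and are excluded from the
#' downstream tests.
#'
#' @param x an [AlleleCounts-class] object (raw counts).
#' @param genes optional subset of genes.
#' @param normalized optional pre-computed result of
#'   [normalizeAlleleCounts()]; computed from `x` when missing.
#' @return list with matrices `f` (frequencies, NA where undefined) and `w`
#'   (raw total reads), both genes x timepoints.
#' @export
alleleFrequency <- function(x, genes = NULL, normalized = NULL) {
  stopifnot(is(x, "AlleleCounts"))
  if (is.null(normalized)) normalized <- normalizeAlleleCounts(x)
  nc <- normalized$counts
  if (!is.null(genes)) {
    x <- x[genes, ]
    nc <- nc[genes, ]
  }
  nref <- refCounts(nc)
  nalt <- altCounts(nc)
  w <- totalCounts(x)
  f <- nref / (nref + nalt)
  f[w == 0] <- NA_real_
  list(f = f, w = w)
}
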