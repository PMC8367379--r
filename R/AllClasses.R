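#' @import methods
#' @importFrom stats median rnbinom rpois rlnorm rbinom runif plogis qlogis
#'   lm pchisq pnorm pt qt sd var cor cor.test kmeans p.adjust glm binomial
#'   coef vcov aov setNames aggregate quantile rnorm complete.cases
#' @importFrom utils read.delim read.csv write.table head tail
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom GenomicRanges GRanges
#' @importMethodsFrom SummarizedExperiment assay assayNames colData
NULL

#' Allele-resolved count timecourse
#'
#' `AlleleCounts` holds per-gene read counts for the two parental alleles of a
#' hybrid diploid across an ordered series of timepoints. It extends
#' \linkS4class{SummarizedExperiment}: rows are genes, columns are timepoints,
#' and the two assays `"ref"` and `"alt"` carry the reads assigned to the
#' reference (common parent) and alternate allele.
#'
#' @slot hybrid single character, a label for the hybrid the counts came from.
#'
#' @section Validity:
#' Exactly the two assays `"ref"` and `"alt"` must be present, with
#' non-negative counts and at least 4 timepoints.
#'
#' @seealso [AlleleCounts()] (constructor), [alleleFrequency()],
#'   [testAseLevels()], [testAseDynamics()]
#' @export
setClass("AlleleCounts",
  contains = "SummarizedExperiment",
  slots = c(hybrid = "character")
)

setValidity("AlleleCounts", function(object) {
  msg <- NULL
  an <- SummarizedExperiment::assayNames(object)
  if (!identical(sort(an), c("alt", "ref")))
    msg <- c(msg, "assays must be exactly 'ref' and 'alt'")
  else {
    if (any(refCounts(object) < 0, na.rm = TRUE) ||
        any(altCounts(object) < 0, na.rm = TRUE))
      msg <- c(msg, "counts must be non-negative")
  }
  if (ncol(object) < 4)
    msg <- c(msg, "at least 4 timepoints are required")
  if (length(object@hybrid) != 1)
    msg <- c(msg, "'hybrid' must be a single label")
  if (is.null(msg)) TRUE else msg
})

#' Construct an AlleleCounts object
#'
#' @param ref,alt integer matrices (genes x timepoints) of reads assigned to
#'   the reference and alternate allele. Dimnames of `ref` are used for genes
#'   and timepoints; `alt` must be conformable.
#' @param timepoints optional numeric sampling times (defaults to
#'   `0:(T-1)`), stored in `colData(x)$time`.
#' @param hybrid label for the hybrid.
#' @return an [AlleleCounts-class] object.
#' @examples
#' ref <- matrix(rpois(40, 50), 10, 4, dimnames = list(paste0("g", 1:10), NULL))
#' ac <- AlleleCounts(ref, ref + 1)
#' dim(ac)
#' @export
AlleleCounts <- function(ref, alt, timepoints = NULL, hybrid = "hybrid") {
  ref <- as.matrix(ref)
  alt <- as.matrix(alt)
  if (!identical(dim(ref), dim(alt)))
    stop("'ref' and 'alt' must have identical dimensions")
  if (is.null(rownames(ref)))
    rownames(ref) <- paste0("gene", seq_len(nrow(ref)))
  dimnames(alt) <- dimnames(ref)
  if (is.null(timepoints)) timepoints <- seq_len(ncol(ref)) - 1
  if (is.null(colnames(ref)))
    colnames(ref) <- colnames(alt) <- paste0("t", timepoints)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ref = ref, alt = alt),
    colData = S4Vectors::DataFrame(time = timepoints,
                                   row.names = colnames(ref)))
  new("AlleleCounts", se, hybrid = hybrid)
}

#' Barcoded CRE-seq count container
#'
#' Holds RNA barcode counts over the reporter timecourse, DNA barcode counts
#' for the library-abundance samples, and the library manifest that links each
#' barcode to its construct (gene, promoter window, allele).
#'
#' @slot rna integer matrix, barcodes x RNA timepoint samples.
#' @slot dna integer matrix, barcodes x DNA samples (usually 2: first and last
#'   timepoint).
#' @slot manifest a [S4Vectors::DataFrame] with at least columns
#'   `construct_id`, `gene`, `region_index`, `allele_label`, `barcode`.
#' @slot time numeric sampling times of the RNA columns.
#' @seealso [CreCounts()], [creExpression()], [filterCres()]
#' @export
setClass("CreCounts",
  slots = c(rna = "matrix", dna = "matrix", manifest = "DataFrame",
            time = "numeric")
)

setValidity("CreCounts", function(object) {
  msg <- NULL
  if (any(object@rna < 0) || any(object@dna < 0))
    msg <- c(msg, "counts must be non-negative")
  if (nrow(object@rna) != nrow(object@dna))
    msg <- c(msg, "rna and dna must index the same barcodes")
  if (!all(c("construct_id", "barcode") %in% colnames(object@manifest)))
    msg <- c(msg, "manifest must have 'construct_id' and 'barcode' columns")
  if (!all(rownames(object@rna) %in% object@manifest$barcode))
    msg <- c(msg, "all counted barcodes must be in the manifest")
  if (length(object@time) != ncol(object@rna))
    msg <- c(msg, "'time' must have one entry per RNA sample")
  if (is.null(msg)) TRUE else msg
})

#' Construct a CreCounts object
#'
#' @param rna,dna count matrices with barcode rownames.
#' @param manifest data.frame or DataFrame describing the library.
#' @param time numeric sampling times for the RNA columns (defaults to
#'   `0:(T-1)`).
#' @return a [CreCounts-class] object.
#' @export
CreCounts <- function(rna, dna, manifest, time = NULL) {
  rna <- as.matrix(rna)
  dna <- as.matrix(dna)
  if (is.null(rownames(rna)))
    stop("'rna' must have barcode rownames")
  dna <- dna[rownames(rna), , drop = FALSE]
  if (is.null(time)) time <- seq_len(ncol(rna)) - 1
  new("CreCounts", rna = rna, dna = dna,
      manifest = S4Vectors::DataFrame(manifest), time = as.numeric(time))
}

#' Position probability matrix with background model
#'
#' A transcription-factor binding motif stored as a position probability
#' matrix (positions x A/C/G/T) together with the background base frequencies
#' used for log-likelihood-ratio scoring. The background is parameterized by
#' its GC fraction; with the default 0.36 the background is
#' p(A) = p(T) = 0.32, p(C) = p(G) = 0.18.
#'
#' @slot name motif identifier.
#' @slot prob numeric matrix, positions x 4, columns A, C, G, T, rows summing
#'   to 1; a pseudocount is applied at construction so all entries are > 0.
#' @slot background length-4 numeric, base frequencies summing to 1.
#' @seealso [Pwm()], [pwmScan()], [bindingChangeScore()]
#' @export
setClass("Pwm",
  slots = c(name = "character", prob = "matrix", background = "numeric")
)

setValidity("Pwm", function(object) {
  msg <- NULL
  if (ncol(object@prob) != 4) msg <- c(msg, "prob must have 4 columns (ACGT)")
  if (any(object@prob <= 0)) msg <- c(msg, "probabilities must be > 0")
  if (any(abs(rowSums(object@prob) - 1) > 1e-9))
    msg <- c(msg, "prob rows must sum to 1")
  if (length(object@background) != 4 ||
      abs(sum(object@background) - 1) > 1e-9)
    msg <- c(msg, "background must be 4 frequencies summing to 1")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn Pwm-class Constructor. `prob` rows are renormalized after
#'   adding `pseudocount`.
#' @param name motif identifier.
#' @param prob positions x 4 probability matrix (columns A, C, G, T).
#' @param backgroundGC GC fraction of the background model (default 0.36).
#' @param pseudocount added to every probability before renormalization.
#' @export
Pwm <- function(name, prob, backgroundGC = 0.36, pseudocount = 1e-3) {
  prob <- as.matrix(prob)
  if (ncol(prob) != 4) stop("'prob' must have 4 columns (A, C, G, T)")
  colnames(prob) <- c("A", "C", "G", "T")
  prob <- prob + pseudocount
  prob <- prob / rowSums(prob)
  new("Pwm", name = as.character(name), prob = prob,
      background = pwmBackground(backgroundGC))
}

#' Background base frequencies from a GC fraction
#'
#' @param gc GC fraction in \[0, 1\].
#' @return named numeric of length 4 (A, C, G, T) summing to 1.
#' @examples
#' pwmBackground(0.36)  # A/T 0.32, C/G 0.18
#' @export
pwmBackground <- function(gc = 0.36) {
  if (gc < 0 || gc > 1) stop("'gc' must be in [0, 1]")
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

setMethod("show", "AlleleCounts", function(object) {
  cat("AlleleCounts of", nrow(object), "genes x", ncol(object),
      "timepoints (hybrid:", object@hybrid, ")\n")
  callNextMethod()
})

setMethod("show", "CreCounts", function(object) {
  cat("CreCounts:", nrow(object@rna), "barcodes,", ncol(object@rna),
      "RNA samples,", ncol(object@dna), "DNA samples;",
      length(unique(object@manifest$construct_id)), "constructs\n")
})

setMethod("show", "Pwm", function(object) {
  cat("Pwm", object@name, "-", nrow(object@prob), "positions, background",
      paste(sprintf("%s=%.2f", names(object@background), object@background),
            collapse = " "), "\n")
})
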