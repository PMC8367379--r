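#' @rdname AlleleCounts-class
#' @param x an `AlleleCounts` object.
#' @export
refCounts <- function(x) SummarizedExperiment::assay(x, "ref")

#' @rdname AlleleCounts-class
#' @export
altCounts <- function(x) SummarizedExperiment::assay(x, "alt")

#' @rdname AlleleCounts-class
#' @export
totalCounts <- function(x) refCounts(x) + altCounts(x)

#' @rdname AlleleCounts-class
#' @export
hybridName <- function(x) x@hybrid

#' @rdname AlleleCounts-class
#' @export
samplingTimes <- function(x) {
  if (is(x, "CreCounts")) return(x@time)
  SummarizedExperiment::colData(x)$time
}

#' @rdname CreCounts-class
#' @param x a `CreCounts` object.
#' @export
rnaCounts <- function(x) x@rna

#' @rdname CreCounts-class
#' @export
dnaCounts <- function(x) x@dna

#' @rdname CreCounts-class
#' @export
libraryManifest <- function(x) x@manifest

#' @rdname Pwm-class
#' @param x a `Pwm` object.
#' @export
pwmProb <- function(x) x@prob

#' @rdname Pwm-class
#' @export
pwmName <- function(x) x@name

#' @rdname Pwm-class
#' @export
motifLength <- function(x) nrow(x@prob)
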