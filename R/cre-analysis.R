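#' Count perfect-match barcodes per sample
#'
#' Exact-string matching of demultiplexed reads against the manifest's
#' barcodes; reads matching no barcode are discarded (their number is kept
#' in the `unmatched` attribute).
#'
#' @param rnaReads list of character vectors of barcode reads, one per RNA
#'   timepoint sample.
#' @param dnaReads list of character vectors, one per DNA sample.
#' @param manifest library manifest with unique `barcode` and
#'   `construct_id` columns.
#' @param time optional sampling times of the RNA samples.
#' @return a [CreCounts-class]; attribute `unmatched` holds per-sample
#'   discarded read counts.
#' @export
countBarcodes <- function(rnaReads, dnaReads, manifest, time = NULL) {
  manifest <- as.data.frame(manifest)
  if (anyDuplicated(manifest$barcode))
    stop("duplicate barcode in the manifest")
  bcs <- manifest$barcode
  tally <- function(reads) {
    idx <- match(reads, bcs)
    c(tabulate(idx, nbins = length(bcs)), sum(is.na(idx)))
  }
  rna <- vapply(rnaReads, tally, numeric(length(bcs) + 1))
  dna <- vapply(dnaReads, tally, numeric(length(bcs) + 1))
  unmatched <- c(rna = unname(rna[length(bcs) + 1, ]),
                 dna = unname(dna[length(bcs) + 1, ]))
  rna <- rna[seq_along(bcs), , drop = FALSE]
  dna <- dna[seq_along(bcs), , drop = FALSE]
  rownames(rna) <- rownames(dna) <- bcs
  colnames(rna) <- paste0("rna_t", seq_along(rnaReads) - 1)
  colnames(dna) <- paste0("dna_", seq_along(dnaReads))
  out <- CreCounts(rna, dna, manifest, time = time)
  attr(out, "unmatched") <- unmatched
  out
}

#' Filter CRE barcodes on coverage
#'
#' A barcode is removed iff it has zero reads in more than a third of the
#' RNA timepoint samples, or fewer than `minMean` reads on average in
#' either the RNA or the DNA samples (strict: a mean of exactly `minMean`
#' is retained).
#'
#' @param x a [CreCounts-class] object.
#' @param minMean minimum mean reads (default 100).
#' @param zeroFraction tolerated fraction of zero RNA samples (default
#'   1/3).
#' @return character vector of retained barcodes.
#' @export
filterCres <- function(x, minMean = 100, zeroFraction = 1 / 3) {
  rna <- rnaCounts(x); dna <- dnaCounts(x)
  keep <- rowSums(rna == 0) <= ncol(rna) * zeroFraction &
    rowMeans(rna) >= minMean & rowMeans(dna) >= minMean
  rownames(rna)[keep]
}

#' Per-barcode CRE expression series
#'
#' Normalizes all RNA and DNA columns jointly by median-of-ratios and
#' returns, per barcode and timepoint, the ratio of normalized RNA to the
#' barcode's DNA reference (the mean of its normalized DNA samples).
#' Zero-count barcodes at a timepoint are treated as missing data; barcodes
#' with a zero DNA reference are dropped and flagged.
#'
#' @param x a [CreCounts-class] object.
#' @param barcodes optional subset (e.g. from [filterCres()]).
#' @return list of class `creExpression` with `expression` (barcodes x
#'   timepoints, NA = missing), `counts` (raw RNA counts), `manifest`,
#'   `time`, `sizeFactors` and `droppedDnaZero`.
#' @export
creExpression <- function(x, barcodes = NULL) {
  stopifnot(is(x, "CreCounts"))
  rna <- rnaCounts(x); dna <- dnaCounts(x)
  if (!is.null(barcodes)) {
    rna <- rna[barcodes, , drop = FALSE]
    dna <- dna[barcodes, , drop = FALSE]
  }
  wide <- cbind(rna, dna)
  sf <- medianOfRatios(wide)
  nrna <- sweep(rna, 2, sf[seq_len(ncol(rna))], "/")
  ndna <- sweep(dna, 2, sf[ncol(rna) + seq_len(ncol(dna))], "/")
  dnaRef <- rowMeans(ndna)
  dropped <- rownames(rna)[dnaRef == 0]
  ok <- dnaRef > 0
  expr <- nrna[ok, , drop = FALSE] / dnaRef[ok]
  expr[rna[ok, , drop = FALSE] == 0] <- NA_real_
  mf <- as.data.frame(libraryManifest(x))
  structure(list(expression = expr,
                 counts = rna[ok, , drop = FALSE],
                 manifest = mf[match(rownames(expr), mf$barcode), ],
                 time = samplingTimes(x), sizeFactors = sf,
                 droppedDnaZero = dropped),
            class = "creExpression")
}

#' @export
print.creExpression <- function(x, ...) {
  cat("creExpression:", nrow(x$expression), "barcodes x",
      ncol(x$expression), "timepoints\n")
  invisible(x)
}

#' Barcode-mean expression series per construct
#'
#' @param ce a `creExpression` object.
#' @param constructs optional subset of construct ids.
#' @return matrix constructs x timepoints of barcode-mean expression
#'   (missing barcodes ignored).
#' @export
constructSeries <- function(ce, constructs = NULL) {
  ids <- ce$manifest$construct_id
  if (is.null(constructs)) constructs <- unique(ids)
  t(vapply(constructs, function(cid) {
    colMeans(ce$expression[ids == cid, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(ce$expression))))
}

#' Map reporter timepoints to RNA-seq timepoints by nearest sampling time
#'
#' For each RNA-seq time, the closest reporter time is chosen; ties go to
#' the earlier sample. The mapping is order-preserving for monotone clocks.
#'
#' @param creTime,rnaTime numeric sampling times.
#' @return integer index into `creTime`, one per `rnaTime`.
#' @export
mapTimepoints <- function(creTime, rnaTime) {
  vapply(rnaTime, function(t) {
    d <- abs(creTime - t)
    which(d == min(d))[1]
  }, integer(1))
}

#' Correlate a CRE region with endogenous expression
#'
#' Pearson correlation of the region's barcode-mean expression series with
#' the endogenous RNA-seq series of its gene, over timepoints mapped by
#' [mapTimepoints()] when the clocks differ.
#'
#' @param creSeries barcode-mean expression over reporter timepoints.
#' @param rnaSeries endogenous expression over RNA-seq timepoints.
#' @param creTime,rnaTime sampling times; equal-length identical clocks by
#'   default.
#' @return list with `r`, `p`, `n` and logical `flagged` (zero variance or
#'   fewer than 3 shared timepoints).
#' @export
correlateWithEndogenous <- function(creSeries, rnaSeries, creTime = NULL,
                                    rnaTime = NULL) {
  if (!is.null(creTime) && !is.null(rnaTime))
    creSeries <- creSeries[mapTimepoints(creTime, rnaTime)]
  ok <- !is.na(creSeries) & !is.na(rnaSeries)
  n <- sum(ok)
  if (n < 3 || sd(creSeries[ok]) == 0 || sd(rnaSeries[ok]) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, flagged = TRUE))
  ct <- cor.test(creSeries[ok], rnaSeries[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n, flagged = FALSE)
}

# Shared two-group machinery: level test on log barcode means, dynamics
# test on the per-timepoint group-A expression share weighted by total raw
# counts.
creGroupTest <- function(expr, counts, group, nPerm = 1000, seed = 1) {
  group <- as.factor(group)
  stopifnot(nlevels(group) == 2, nrow(expr) == length(group))
  nA <- sum(group == levels(group)[1])
  nB <- sum(group == levels(group)[2])
  lev <- list(p = NA_real_, estimate = NA_real_, untestable = TRUE)
  if (nA >= 2 && nB >= 2) {
    bcMean <- rowMeans(expr, na.rm = TRUE)
    if (all(bcMean > 0)) {
      fit <- summary(lm(log(bcMean) ~ group))$coefficients
      lev <- list(p = fit[2, 4], estimate = fit[2, 1], untestable = FALSE)
    }
  }
  a <- group == levels(group)[1]
  muA <- colMeans(expr[a, , drop = FALSE], na.rm = TRUE)
  muB <- colMeans(expr[!a, , drop = FALSE], na.rm = TRUE)
  share <- muA / (muA + muB)
  w <- colSums(counts, na.rm = TRUE)
  dyn <- testAseDynamics(share, w, nPerm = nPerm, seed = seed)
  list(level = lev, dynamics = dyn, groups = levels(group),
       n_barcodes = c(nA, nB))
}

#' Test expression-level differences between two CRE alleles
#'
#' One summary value per barcode (the natural log of its across-timepoint
#' mean expression) enters a linear model with an allele indicator; this is
#' deliberately conservative, so a single barcode with a global offset
#' cannot masquerade as a signal. Requires >= 2 barcodes per allele.
#'
#' @param ce a `creExpression` object.
#' @param barcodes barcodes to use (two groups).
#' @param group allele label per barcode.
#' @return list with `p`, `estimate` (log ratio) and `untestable`.
#' @export
testCreLevels <- function(ce, barcodes, group) {
  expr <- ce$expression[barcodes, , drop = FALSE]
  counts <- ce$counts[barcodes, , drop = FALSE]
  creGroupTest(expr, counts, group, nPerm = 2)$level
}

#' Test expression-dynamics differences between two CRE alleles
#'
#' Per timepoint, the first allele's expression share
#' muA / (muA + muB) is computed from barcode-mean expression, weighted by
#' the total raw counts at that timepoint, and the weighted Durbin-Watson
#' dynamics test ([testAseDynamics()]) is applied to the share series.
#'
#' @inheritParams testCreLevels
#' @param nPerm,seed permutation settings for the dynamics p-value.
#' @return a dynamics result list (`dw`, `p`, `untestable`).
#' @export
testCreDynamics <- function(ce, barcodes, group, nPerm = 1000, seed = 1) {
  expr <- ce$expression[barcodes, , drop = FALSE]
  counts <- ce$counts[barcodes, , drop = FALSE]
  creGroupTest(expr, counts, group, nPerm = nPerm, seed = seed)$dynamics
}

# Genotype of a construct at a focal variant, derived from its allele
# label. Swap constructs for other variants carry their background's
# allele at the focal variant; chimeras are NA here.
genotypeAtVariant <- function(alleleLabel, focalId) {
  vapply(alleleLabel, function(lab) {
    if (lab == "P1") return("P1")
    if (lab == "P2") return("P2")
    if (grepl("^swap:.*:(P2inP1|P1inP2)$", lab)) {
      dir <- sub("^swap:.*:(P2inP1|P1inP2)$", "\\1", lab)
      vid <- sub("^swap:(.*):(P2inP1|P1inP2)$", "\\1", lab)
      if (vid == focalId)
        return(if (dir == "P2inP1") "P2" else "P1")
      return(if (dir == "P2inP1") "P1" else "P2")
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Test individual variants of a CRE region
#'
#' Constructs of the region (parental plus swap constructs with an
#' unambiguous allele at the focal variant) are pooled by their genotype at
#' each variant in turn, and level and dynamics differences are tested
#' between the two genotype groups.
#'
#' @param ce a `creExpression` object.
#' @param region manifest rows of one region (gene x region_index), with
#'   retained barcodes.
#' @param variantIds variants to test (default: all named in the region's
#'   `variant_ids`).
#' @param nPerm,seed permutation settings.
#' @return data.frame, one row per variant: p_level, p_dyn, n_P1, n_P2,
#'   untestable.
#' @export
testVariant <- function(ce, region, variantIds = NULL, nPerm = 1000,
                        seed = 1) {
  region <- as.data.frame(region)
  if (is.null(variantIds)) {
    variantIds <- unique(unlist(strsplit(
      region$variant_ids[region$allele_label == "P1"], ";")))
    variantIds <- variantIds[nzchar(variantIds)]
  }
  out <- lapply(variantIds, function(vid) {
    geno <- genotypeAtVariant(region$allele_label, vid)
    use <- !is.na(geno) & region$barcode %in% rownames(ce$expression)
    if (length(unique(geno[use])) < 2)
      return(data.frame(variant = vid, p_level = NA, est_level = NA,
                        dw = NA, p_dyn = NA, n_P1 = sum(geno[use] == "P1"),
                        n_P2 = sum(geno[use] == "P2"), untestable = TRUE))
    gt <- creGroupTest(ce$expression[region$barcode[use], , drop = FALSE],
                       ce$counts[region$barcode[use], , drop = FALSE],
                       geno[use], nPerm = nPerm, seed = seed)
    data.frame(variant = vid, p_level = gt$level$p,
               est_level = gt$level$estimate, dw = gt$dynamics$dw,
               p_dyn = gt$dynamics$p, n_P1 = gt$n_barcodes[1],
               n_P2 = gt$n_barcodes[2],
               untestable = gt$dynamics$untestable)
  })
  do.call(rbind, out)
}

#' Map a parental expression difference to the proximal or distal half
#'
#' Using the chimeric constructs, barcodes are grouped once by the origin
#' of the proximal (TSS-side) half and once by the origin of the distal
#' half, and the dynamics test is run for each grouping. The difference
#' maps to the proximal region if the proximal but not the distal genotype
#' is significant, and conversely; otherwise `both` or `neither`.
#'
#' @param ce a `creExpression` object.
#' @param region manifest rows of one region including `P1`, `P2`,
#'   `chimera:P1-P2` (distal P1, proximal P2) and `chimera:P2-P1` rows.
#' @param alpha significance cutoff applied to the test p-values.
#' @param nPerm,seed permutation settings.
#' @return list with `parental`, `proximal`, `distal` test results and
#'   `classification` (`proximal`, `distal`, `both`, `neither`, or `NA`
#'   when chimeras are missing).
#' @export
mapChimera <- function(ce, region, alpha = 0.05, nPerm = 1000, seed = 1) {
  region <- as.data.frame(region)
  region <- region[region$barcode %in% rownames(ce$expression), ]
  lab <- region$allele_label
  need <- c("P1", "P2", "chimera:P1-P2", "chimera:P2-P1")
  if (!all(need %in% lab))
    return(list(parental = NULL, proximal = NULL, distal = NULL,
                classification = NA_character_))
  grp <- function(g) {
    use <- lab %in% names(g)
    creGroupTest(ce$expression[region$barcode[use], , drop = FALSE],
                 ce$counts[region$barcode[use], , drop = FALSE],
                 unname(g[lab[use]]), nPerm = nPerm, seed = seed)
  }
  parental <- grp(c("P1" = "A", "P2" = "B"))
  proximal <- grp(c("P1" = "A", "chimera:P2-P1" = "A",
                    "P2" = "B", "chimera:P1-P2" = "B"))
  distal <- grp(c("P1" = "A", "chimera:P1-P2" = "A",
                  "P2" = "B", "chimera:P2-P1" = "B"))
  ps <- proximal$dynamics$p < alpha
  ds <- distal$dynamics$p < alpha
  classification <- if (is.na(ps) || is.na(ds)) NA_character_
    else if (ps && !ds) "proximal"
    else if (ds && !ps) "distal"
    else if (ps && ds) "both" else "neither"
  list(parental = parental, proximal = proximal, distal = distal,
       classification = classification)
}

#' Classify a chimera as inside or outside the parental expression range
#'
#' Computes the Euclidean distance between the two parental series (d_pp)
#' and the mean of the chimera's distances to each parent (d_cp); the
#' chimera is `outside` iff d_cp > d_pp. Also counts the timepoints at
#' which the chimera's value lies strictly outside the interval spanned by
#' the two parents. Missing timepoints are dropped; all series are
#' restricted to their common defined timepoints.
#'
#' @param parent1,parent2,chimera expression series on a common clock.
#' @return list with `range` ("inside"/"outside"), `d_pp`, `d_cp_mean`,
#'   `n_outside_timepoints`, `n_timepoints`.
#' @export
classifyChimeraRange <- function(parent1, parent2, chimera) {
  ok <- !is.na(parent1) & !is.na(parent2) & !is.na(chimera)
  p1 <- parent1[ok]; p2 <- parent2[ok]; ch <- chimera[ok]
  dpp <- sqrt(sum((p1 - p2)^2))
  dcp <- mean(c(sqrt(sum((ch - p1)^2)), sqrt(sum((ch - p2)^2))))
  lo <- pmin(p1, p2); hi <- pmax(p1, p2)
  nOut <- sum(ch < lo | ch > hi)
  list(range = if (dcp > dpp) "outside" else "inside",
       d_pp = dpp, d_cp_mean = dcp, n_outside_timepoints = nOut,
       n_timepoints = sum(ok))
}

#' Summarize significant variants by type
#'
#' Tallies tested and significant SNPs and InDels from a variant test table
#' and reports the ratio of significant SNPs to significant InDels.
#'
#' @param results data.frame with columns `type` (`SNP` or `InDel`/`INS`/
#'   `DEL`) and either a logical `significant` or a `q` column.
#' @param fdr cutoff applied to `q` when no `significant` column exists.
#' @return list with `n_snp_sig`, `n_snp_tested`, `n_indel_sig`,
#'   `n_indel_tested` and `snp_indel_ratio`.
#' @export
summarizeVariantTests <- function(results, fdr = 0.05) {
  type <- ifelse(results$type == "SNP", "SNP", "InDel")
  sig <- if (!is.null(results$significant)) results$significant
    else results$q < fdr
  list(n_snp_sig = sum(sig & type == "SNP", na.rm = TRUE),
       n_snp_tested = sum(type == "SNP"),
       n_indel_sig = sum(sig & type == "InDel", na.rm = TRUE),
       n_indel_tested = sum(type == "InDel"),
       snp_indel_ratio = sum(sig & type == "SNP", na.rm = TRUE) /
         sum(sig & type == "InDel", na.rm = TRUE))
}
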