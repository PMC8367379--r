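#' Define upstream, coding and downstream regions per gene
#'
#' The upstream region is the sequence between a gene's CDS and the adjacent
#' CDS on its 5' side; when that gap is shorter than `minGap` (default 5 bp)
#' or the coding sequences overlap, the region is extended past it to the
#' next upstream gene. The downstream region is `downstreamLen` (default 80)
#' bp 3' of the stop codon, clipped at contig ends. The coding region is the
#' CDS span. All intervals are 1-based closed on the gene's strand.
#'
#' @param annotation a `GRanges` of CDS features with an `ID` metadata
#'   column (one CDS per gene; features with `type` present are subset to
#'   `type == "CDS"`).
#' @param contigLengths named integer vector of contig lengths.
#' @param downstreamLen downstream region length (bp).
#' @param minGap minimum usable intergenic gap (bp).
#' @return a `GRanges` with metadata columns `gene`, `region`
#'   (upstream/coding/downstream) and `clipped`.
#' @export
defineRegions <- function(annotation, contigLengths, downstreamLen = 80,
                          minGap = 5) {
  cds <- annotation
  if (!is.null(cds$type)) cds <- cds[cds$type == "CDS"]
  if (length(cds) == 0) stop("no CDS features in the annotation")
  if (is.null(cds$ID)) stop("CDS features need an 'ID' column")
  out <- list()
  for (chr in unique(as.character(GenomicRanges::seqnames(cds)))) {
    if (!chr %in% names(contigLengths))
      stop("no length known for contig ", chr)
    clen <- contigLengths[[chr]]
    cc <- cds[GenomicRanges::seqnames(cds) == chr]
    cc <- cc[order(GenomicRanges::start(cc))]
    st <- GenomicRanges::start(cc)
    en <- GenomicRanges::end(cc)
    strd <- as.character(GenomicRanges::strand(cc))
    for (i in seq_along(cc)) {
      gene <- cc$ID[i]
      plus <- strd[i] == "+"
      # upstream: walk 5'-adjacent CDSs until the gap is usable
      if (plus) {
        j <- i - 1
        while (j >= 1 && st[i] - en[j] - 1 < minGap) j <- j - 1
        upStart <- if (j >= 1) en[j] + 1 else 1
        upEnd <- st[i] - 1
        upOk <- upEnd >= upStart
        dnStart <- en[i] + 1
        dnEnd <- min(en[i] + downstreamLen, clen)
        clipped <- en[i] + downstreamLen > clen
      } else {
        j <- i + 1
        while (j <= length(cc) && st[j] - en[i] - 1 < minGap) j <- j + 1
        upStart <- en[i] + 1
        upEnd <- if (j <= length(cc)) st[j] - 1 else clen
        upOk <- upEnd >= upStart
        dnEnd <- st[i] - 1
        dnStart <- max(st[i] - downstreamLen, 1)
        clipped <- st[i] - downstreamLen < 1
      }
      rows <- data.frame(
        start = c(if (upOk) upStart else st[i], st[i], dnStart),
        end = c(if (upOk) upEnd else st[i] - 1, en[i], dnEnd),
        region = c("upstream", "coding", "downstream"),
        clipped = c(FALSE, FALSE, clipped))
      rows <- rows[rows$end >= rows$start, , drop = FALSE]
      gr <- GenomicRanges::GRanges(chr,
              IRanges::IRanges(rows$start, rows$end), strand = strd[i])
      gr$gene <- gene
      gr$region <- rows$region
      gr$clipped <- rows$clipped
      out[[length(out) + 1]] <- gr
    }
  }
  unname(do.call(c, out))
}

#' Count variants per gene region
#'
#' A variant counts in a region iff the position of its leftmost reference
#' base lies inside the interval (InDels are assigned by their leftmost
#' base, independent of strand). SNPs and InDels (INS or DEL) are tallied
#' separately.
#'
#' @param variants data.frame with columns chrom, pos (1-based), type
#'   (`SNP`, `INS`, `DEL`).
#' @param regions output of [defineRegions()].
#' @return data.frame, one row per gene, with columns
#'   `<region>_snp` and `<region>_indel` for upstream, coding, downstream.
#' @export
countRegionVariants <- function(variants, regions) {
  known <- unique(as.character(GenomicRanges::seqnames(regions)))
  if (nrow(variants) > 0 && !all(variants$chrom %in% known))
    stop("variant on unknown contig: ",
         paste(setdiff(unique(variants$chrom), known), collapse = ", "))
  genes <- unique(regions$gene)
  cols <- as.vector(outer(c("upstream", "coding", "downstream"),
                          c("snp", "indel"), paste, sep = "_"))
  counts <- matrix(0L, length(genes), length(cols),
                   dimnames = list(genes, cols))
  if (nrow(variants) > 0) {
    vgr <- GenomicRanges::GRanges(variants$chrom,
             IRanges::IRanges(variants$pos, width = 1))
    hits <- GenomicRanges::findOverlaps(vgr, regions, ignore.strand = TRUE)
    if (length(hits)) {
      vt <- ifelse(variants$type[S4Vectors::queryHits(hits)] == "SNP",
                   "snp", "indel")
      key <- paste(regions$gene[S4Vectors::subjectHits(hits)],
                   paste(regions$region[S4Vectors::subjectHits(hits)], vt,
                         sep = "_"))
      tab <- table(key)
      parts <- strsplit(names(tab), " ")
      for (i in seq_along(tab))
        counts[parts[[i]][1], parts[[i]][2]] <-
          counts[parts[[i]][1], parts[[i]][2]] + as.integer(tab[i])
    }
  }
  data.frame(gene = genes, counts, row.names = NULL)
}

#' Logistic regression of ASE status on variant burden
#'
#' Fits logit P(ASE) = b0 + b1 x by maximum likelihood (IRLS via
#' `stats::glm`), with Wald 95% confidence interval and p-value for b1. The
#' odds ratio `exp(b1)` is reported per additional variant. Complete
#' separation or a constant predictor is flagged and no Wald interval is
#' reported.
#'
#' @param ase logical (or 0/1) ASE status per gene.
#' @param x numeric variant count per gene.
#' @return one-row data.frame: b0, b1, or_, ci_lo, ci_hi, p, flagged.
#' @export
logisticAssociation <- function(ase, x) {
  ase <- as.logical(ase)
  ok <- !is.na(ase) & !is.na(x)
  ase <- ase[ok]; x <- x[ok]
  if (sum(ase) < 2 || sum(!ase) < 2)
    stop("need at least 2 genes in each outcome class")
  if (length(unique(x)) < 2)
    return(data.frame(b0 = NA, b1 = NA, or_ = NA, ci_lo = NA, ci_hi = NA,
                      p = NA, flagged = TRUE))
  fit <- suppressWarnings(glm(ase ~ x, family = binomial()))
  b <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  sep <- !fit$converged || any(abs(b) > 15) || any(se > 100)
  if (sep)
    return(data.frame(b0 = b[1], b1 = b[2], or_ = exp(b[2]), ci_lo = NA,
                      ci_hi = NA, p = NA, flagged = TRUE))
  z <- b[2] / se[2]
  data.frame(b0 = unname(b[1]), b1 = unname(b[2]), or_ = exp(unname(b[2])),
             ci_lo = exp(b[2] - 1.959964 * se[2]),
             ci_hi = exp(b[2] + 1.959964 * se[2]),
             p = 2 * pnorm(-abs(z)), flagged = FALSE, row.names = NULL)
}

#' Battery of variant-burden regressions with Bonferroni control
#'
#' Runs [logisticAssociation()] for every predictor column (typically the 6
#' per-region SNP and InDel counts) against every response column (typically
#' ASE levels and dynamics status in each of 5 hybrids), 60 regressions in
#' the standard battery, and flags significance at the Bonferroni-corrected
#' level `alpha / (#predictors * #responses)`. Genes with missing variant
#' counts are dropped from the fits.
#'
#' @param aseStatus logical matrix or data.frame, genes x responses.
#' @param variantCounts numeric matrix or data.frame, genes x predictors.
#' @param alpha family-wise error target (default 0.05).
#' @return data.frame with one row per predictor x response pair, including
#'   the Bonferroni threshold used and a `significant` flag.
#' @export
associationBattery <- function(aseStatus, variantCounts, alpha = 0.05) {
  aseStatus <- as.data.frame(aseStatus)
  variantCounts <- as.data.frame(variantCounts)
  stopifnot(nrow(aseStatus) == nrow(variantCounts))
  nTests <- ncol(aseStatus) * ncol(variantCounts)
  thr <- alpha / nTests
  res <- list()
  for (resp in colnames(aseStatus)) {
    for (pred in colnames(variantCounts)) {
      fit <- logisticAssociation(aseStatus[[resp]], variantCounts[[pred]])
      res[[length(res) + 1]] <- cbind(
        data.frame(predictor = pred, response = resp), fit)
    }
  }
  out <- do.call(rbind, res)
  out$n_tests <- nTests
  out$bonferroni <- thr
  out$significant <- !is.na(out$p) & out$p < thr
  rownames(out) <- NULL
  out
}
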