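#' Default oligo layout parts for the CRE-seq library
#'
#' The 200 bp synthetic oligo layout is: forward primer, RS1, CRE, RS2,
#' (pad,) RS3, RS4, barcode, RS5, reverse primer, where RS1-RS5 are
#' restriction sites. With 15 bp primers, 6 bp sites, a 130 bp CRE and a
#' 10 bp barcode the parts sum to exactly 200; InDel-gapped alleles receive
#' a pad between RS2 and RS3 to keep the length constant.
#'
#' @return named list with `fwd`, `rev`, `rs` (named character of 5 sites),
#'   and `oligoLen`.
#' @export
creDesignParts <- function() {
  list(fwd = "ACAGGACACGCGTAC", rev = "GTCACGCTGACGGTA",
       rs = c(RS1 = "GAATTC", RS2 = "GGATCC", RS3 = "TCTAGA",
              RS4 = "GTCGAC", RS5 = "CTGCAG"),
       oligoLen = 200L)
}

#' Tile sliding windows across a promoter target region
#'
#' Generates `window`-bp windows at `step`-bp offsets across the
#' `upstreamLen` bp immediately upstream of a TSS, on the coding strand,
#' numbered proximal (0, ending at the TSS) to distal. Windows that fall
#' outside the contig or overlap coding sequence of the next upstream gene
#' (`cdsMask`) are removed; the default geometry (250/130/30) yields five
#' windows.
#'
#' @param tss TSS position (1-based).
#' @param strand `"+"` or `"-"`.
#' @param chrom contig name.
#' @param upstreamLen length of the target region upstream of the TSS.
#' @param window window length (bp).
#' @param step offset between successive windows (bp).
#' @param cdsMask optional `GRanges` of coding sequence to avoid.
#' @param contigLength contig length for boundary clipping.
#' @return `GRanges` of windows with metadata column `region_index`
#'   (0 = proximal); zero windows (with a warning) when
#'   `upstreamLen < window`.
#' @export
makeWindows <- function(tss, strand = "+", chrom = "chrI",
                        upstreamLen = 250, window = 130, step = 30,
                        cdsMask = NULL, contigLength = Inf) {
  if (upstreamLen < window) {
    warning("upstream target shorter than the window: no windows")
    return(GenomicRanges::GRanges())
  }
  nWin <- floor((upstreamLen - window) / step) + 1
  offs <- (seq_len(nWin) - 1) * step
  if (strand == "+") {
    starts <- tss - window - offs
    ends <- tss - 1 - offs
  } else {
    starts <- tss + 1 + offs
    ends <- tss + window + offs
  }
  keep <- starts >= 1 & ends <= contigLength
  gr <- GenomicRanges::GRanges(chrom,
          IRanges::IRanges(starts[keep], ends[keep]), strand = strand)
  gr$region_index <- offs[keep] / step
  if (!is.null(cdsMask) && length(gr) > 0) {
    hit <- IRanges::overlapsAny(gr, cdsMask, ignore.strand = TRUE)
    gr <- gr[!hit]
  }
  gr
}

#' Generate a barcode set
#'
#' Random fixed-length barcodes with minimum pairwise Hamming distance
#' `minDist`, containing no forbidden (restriction) site on either strand,
#' and with per-base composition across the whole set within 10 percentage
#' points of uniform.
#'
#' @param n number of barcodes.
#' @param length barcode length (default 10).
#' @param minDist minimum pairwise Hamming distance (default 2).
#' @param forbiddenSites character vector of sites to exclude (checked on
#'   both strands).
#' @param seed seed.
#' @param maxTries candidate draws before giving up.
#' @return character vector of `n` barcodes.
#' @export
generateBarcodes <- function(n, length = 10, minDist = 2,
                             forbiddenSites = character(), seed = 1,
                             maxTries = 200 * n + 10000) {
  bases <- c("A", "C", "G", "T")
  pats <- if (base::length(forbiddenSites))
    unique(c(forbiddenSites, revComp(forbiddenSites))) else character(0)
  accepted <- character(n)
  nAcc <- 0
  acceptedMat <- NULL
  # for minDist 2 a hash of one-position-wildcarded patterns detects any
  # pair at Hamming distance <= 1 in O(length) per candidate
  seen <- new.env(hash = TRUE, size = as.integer(2 * n * length + 16))
  withSeed(childSeed(seed, "barcodes"), {
    tries <- 0
    while (nAcc < n && tries < maxTries) {
      batch <- min(2 * (n - nAcc) + 100, maxTries - tries)
      tries <- tries + batch
      cands <- vapply(seq_len(batch), function(i)
        paste(sample(bases, length, replace = TRUE), collapse = ""),
        character(1))
      for (p in pats) cands <- cands[!grepl(p, cands, fixed = TRUE)]
      for (cand in cands) {
        if (nAcc >= n) break
        if (minDist <= 2) {
          keys <- vapply(seq_len(length), function(i) {
            s <- cand; substr(s, i, i) <- "."; paste0(i, s)
          }, character(1))
          if (any(vapply(keys, exists, logical(1), envir = seen,
                         inherits = FALSE)))
            next
          for (k in keys) assign(k, TRUE, envir = seen)
        } else {
          cm <- strsplit(cand, "")[[1]]
          if (!is.null(acceptedMat) &&
              any(colSums(acceptedMat != cm) < minDist))
            next
          acceptedMat <- cbind(acceptedMat, cm)
        }
        nAcc <- nAcc + 1
        accepted[nAcc] <- cand
      }
    }
  })
  accepted <- accepted[seq_len(nAcc)]
  if (base::length(accepted) < n)
    stop("barcode constraint space exhausted: got ", base::length(accepted),
         " of ", n)
  comp <- table(factor(unlist(strsplit(accepted, "")), levels = bases))
  frac <- comp / sum(comp)
  # composition bias is only assessable on a reasonably sized set
  if (sum(comp) >= 200 && any(abs(frac - 0.25) > 0.10))
    stop("barcode base composition biased beyond 10 percentage points")
  accepted
}

#' Pairwise minimum Hamming distance of a barcode set
#'
#' Exhaustive O(n^2) verification helper.
#'
#' @param barcodes character vector of equal-length barcodes.
#' @return the minimum pairwise Hamming distance.
#' @export
minPairwiseHamming <- function(barcodes) {
  m <- do.call(rbind, strsplit(barcodes, ""))
  best <- ncol(m)
  for (i in seq_len(nrow(m) - 1)) {
    d <- rowSums(m[(i + 1):nrow(m), , drop = FALSE] !=
                 matrix(m[i, ], nrow(m) - i, ncol(m), byrow = TRUE))
    best <- min(best, d)
    if (best == 0) break
  }
  best
}

# Apply a subset of variants to a window sequence; positions are genomic
# (1-based), windowStart anchors the window on the same coordinates.
applyWindowVariants <- function(winSeq, variants, windowStart) {
  if (is.null(variants) || nrow(variants) == 0) return(winSeq)
  v <- variants
  rel <- v$pos - windowStart + 1
  if (any(rel < 1 | rel > nchar(winSeq)))
    stop("variant coordinates outside the window")
  v$pos <- rel
  applyVariants(winSeq, v)
}

#' Build parental and single-variant-swap alleles for one CRE window
#'
#' With k variants in the window: k = 0 gives one shared construct; k = 1
#' gives the two parental constructs (which differ by that variant); k >= 2
#' additionally gives 2k swap constructs, each parental background with
#' exactly one variant replaced by the other strain's allele (2 + 2k
#' total).
#'
#' @param p1seq window sequence of parent 1 (genome orientation).
#' @param variants data.frame of variants inside the window (chrom, pos,
#'   ref, alt, type; 1-based genomic coordinates); parent 2 carries all
#'   `alt` alleles.
#' @param windowStart genomic start of the window (1-based).
#' @param strand window strand; for `"-"` the returned CRE sequences are
#'   reverse-complemented into coding-strand orientation.
#' @return data.frame with columns `allele_label`, `variant_ids`, `cre_seq`.
#' @export
buildAlleles <- function(p1seq, variants, windowStart, strand = "+") {
  k <- if (is.null(variants)) 0 else nrow(variants)
  orient <- function(s) if (strand == "-") revComp(s) else s
  if (k == 0)
    return(data.frame(allele_label = "shared", variant_ids = "",
                      cre_seq = orient(p1seq)))
  vid <- if (!is.null(variants$id)) variants$id else
    paste0(variants$chrom, "_", variants$pos)
  p2seq <- applyWindowVariants(p1seq, variants, windowStart)
  out <- data.frame(allele_label = c("P1", "P2"),
                    variant_ids = paste(vid, collapse = ";"),
                    cre_seq = c(orient(p1seq), orient(p2seq)))
  if (k >= 2) {
    for (i in seq_len(k)) {
      s1 <- applyWindowVariants(p1seq, variants[i, , drop = FALSE],
                                windowStart)
      s2 <- applyWindowVariants(p1seq, variants[-i, , drop = FALSE],
                                windowStart)
      out <- rbind(out, data.frame(
        allele_label = c(sprintf("swap:%s:P2inP1", vid[i]),
                         sprintf("swap:%s:P1inP2", vid[i])),
        variant_ids = vid[i],
        cre_seq = c(orient(s1), orient(s2))))
    }
  }
  out
}

#' Build the two chimeric alleles of a CRE window
#'
#' Globally aligns the two parental alleles, splits at the alignment
#' midpoint column, and recombines: chimera A carries the left (distal)
#' half of parent 1 and the right (proximal) half of parent 2; chimera B is
#' the converse. Gaps are removed after recombination.
#'
#' @param p1seq,p2seq parental CRE sequences (coding-strand orientation).
#' @param minIdentity refuse alignment identities below this fraction
#'   (default 0.5), which indicate mis-paired regions.
#' @return data.frame with `allele_label` (`chimera:P1-P2`,
#'   `chimera:P2-P1`), `cre_seq`, and the alignment `split_column` and
#'   `identity` as attributes.
#' @export
buildChimeras <- function(p1seq, p2seq, minIdentity = 0.5) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(p1seq), Biostrings::DNAString(p2seq),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1),
    gapOpening = 2, gapExtension = 1)
  ap <- as.character(Biostrings::alignedPattern(aln))
  as_ <- as.character(Biostrings::alignedSubject(aln))
  L <- nchar(ap)
  ident <- sum(strsplit(ap, "")[[1]] == strsplit(as_, "")[[1]]) / L
  if (ident < minIdentity)
    stop("alignment identity ", round(ident, 2),
         " below ", minIdentity, ": refusing to build chimeras")
  mid <- ceiling(L / 2)
  strip <- function(s) gsub("-", "", s, fixed = TRUE)
  out <- data.frame(
    allele_label = c("chimera:P1-P2", "chimera:P2-P1"),
    variant_ids = "",
    cre_seq = c(strip(paste0(substr(ap, 1, mid), substr(as_, mid + 1, L))),
                strip(paste0(substr(as_, 1, mid), substr(ap, mid + 1, L)))))
  attr(out, "split_column") <- mid
  attr(out, "identity") <- ident
  out
}

# Deterministic pseudo-random pad sequence, seeded by construct id and
# screened against restriction sites on both strands.
padSequence <- function(len, id, sites) {
  if (len == 0) return("")
  for (try in 1:100) {
    pad <- withSeed(childSeed(try, paste0("pad_", id)),
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""))
    if (!any(containsSite(pad, sites))) return(pad)
  }
  stop("could not generate a site-free pad of length ", len)
}

#' Assemble a 200 bp oligo from its parts
#'
#' Concatenates forward primer, RS1, CRE, RS2, pad, RS3, RS4, barcode, RS5,
#' reverse primer. Errors if any restriction site occurs inside the CRE or
#' the barcode (either strand) or if the assembled length differs from the
#' layout's `oligoLen`.
#'
#' @param creSeq the CRE sequence.
#' @param barcode the 10 bp barcode.
#' @param pad pad sequence for gapped alleles (possibly "").
#' @param parts layout from [creDesignParts()].
#' @return the oligo sequence (single character string).
#' @export
assembleOligo <- function(creSeq, barcode, pad = "",
                          parts = creDesignParts()) {
  if (any(containsSite(creSeq, parts$rs)))
    stop("restriction site inside the CRE sequence")
  if (any(containsSite(barcode, parts$rs)))
    stop("restriction site inside the barcode")
  oligo <- paste0(parts$fwd, parts$rs["RS1"], creSeq, parts$rs["RS2"], pad,
                  parts$rs["RS3"], parts$rs["RS4"], barcode,
                  parts$rs["RS5"], parts$rev)
  if (nchar(oligo) != parts$oligoLen)
    stop("assembled oligo is ", nchar(oligo), " bp, expected ",
         parts$oligoLen)
  oligo
}

#' Parse an assembled oligo back into its parts
#'
#' Inverse of [assembleOligo()] given the same layout.
#'
#' @param oligo the oligo sequence.
#' @param parts layout from [creDesignParts()].
#' @param barcodeLen barcode length.
#' @return list with `cre`, `pad`, `barcode`.
#' @export
parseOligo <- function(oligo, parts = creDesignParts(), barcodeLen = 10) {
  nf <- nchar(parts$fwd); nr <- nchar(parts$rev)
  rs <- parts$rs
  tailLen <- nchar(rs["RS3"]) + nchar(rs["RS4"]) + barcodeLen +
    nchar(rs["RS5"]) + nr
  bcStart <- nchar(oligo) - nr - nchar(rs["RS5"]) - barcodeLen + 1
  mid <- substr(oligo, nf + nchar(rs["RS1"]) + 1, nchar(oligo) - tailLen)
  # mid = CRE + RS2 + pad; RS2 marks the CRE end (CRE itself is site-free)
  rs2at <- regexpr(rs["RS2"], mid, fixed = TRUE)
  if (rs2at < 0) stop("RS2 not found: not a library oligo")
  list(cre = substr(mid, 1, rs2at - 1),
       pad = substr(mid, rs2at + nchar(rs["RS2"]), nchar(mid)),
       barcode = substr(oligo, bcStart, bcStart + barcodeLen - 1))
}

#' Design a complete barcoded CRE-seq library
#'
#' For each gene: tile promoter windows upstream of its TSS
#' ([makeWindows()]), build parental, single-variant-swap
#' ([buildAlleles()]) and optionally chimeric ([buildChimeras()])
#' constructs, attach `nBarcodes` barcode replicates per construct, and
#' assemble fixed-length oligos with pads for gapped alleles. Windows whose
#' CRE contains a restriction site are skipped (site-free target regions
#' are a design criterion).
#'
#' @param genome `DNAStringSet` of parent-1 contigs.
#' @param tss data.frame with columns gene, chrom, pos, strand.
#' @param variants data.frame (chrom, pos, ref, alt, type) of parent-2
#'   differences on parent-1 coordinates.
#' @param cdsMask optional `GRanges` of coding sequence to avoid in
#'   windows.
#' @param chimeras also build chimeric alleles for windows with variants.
#' @param nBarcodes barcode replicates per construct (default 4).
#' @param upstreamLen,window,step window geometry (defaults 250/130/30).
#' @param parts oligo layout from [creDesignParts()].
#' @param seed seed (barcodes and pads).
#' @return manifest data.frame: construct_id, gene, region_index,
#'   allele_label, variant_ids, barcode, pad_len, cre_seq, oligo_seq.
#' @export
designLibrary <- function(genome, tss, variants, cdsMask = NULL,
                          chimeras = FALSE, nBarcodes = 4,
                          upstreamLen = 250, window = 130, step = 30,
                          parts = creDesignParts(), seed = 1) {
  rows <- list()
  for (i in seq_len(nrow(tss))) {
    g <- tss[i, ]
    wins <- makeWindows(g$pos, g$strand, g$chrom, upstreamLen, window,
                        step, cdsMask,
                        contigLength = length(genome[[g$chrom]]))
    for (j in seq_along(wins)) {
      ws <- GenomicRanges::start(wins)[j]
      we <- GenomicRanges::end(wins)[j]
      p1seq <- as.character(Biostrings::subseq(genome[[g$chrom]], ws, we))
      if (any(containsSite(p1seq, parts$rs))) next
      vin <- variants[variants$chrom == g$chrom & variants$pos >= ws &
                        variants$pos <= we, , drop = FALSE]
      alle <- buildAlleles(p1seq, vin, ws, strand = g$strand)
      if (chimeras && nrow(vin) >= 1) {
        p2 <- alle$cre_seq[alle$allele_label == "P2"]
        p1 <- alle$cre_seq[alle$allele_label == "P1"]
        alle <- rbind(alle, buildChimeras(p1, p2))
      }
      alle$gene <- g$gene
      alle$region_index <- wins$region_index[j]
      rows[[length(rows) + 1]] <- alle
    }
  }
  if (!length(rows)) stop("no designable windows")
  lib <- do.call(rbind, rows)
  lib$construct_id <- sprintf("%s_r%d_%s", lib$gene, lib$region_index,
                              lib$allele_label)
  # insertion-carrying alleles exceed the window: trim from the distal
  # (left) end so every CRE is anchored at its TSS-proximal end; deletion
  # carriers are shorter and receive a pad
  lib$cre_seq <- vapply(lib$cre_seq, function(s) {
    if (nchar(s) > window) substr(s, nchar(s) - window + 1, nchar(s)) else s
  }, character(1), USE.NAMES = FALSE)
  lib <- lib[rep(seq_len(nrow(lib)), each = nBarcodes), , drop = FALSE]
  lib$barcode <- generateBarcodes(nrow(lib), forbiddenSites = parts$rs,
                                  seed = seed)
  lib$pad_len <- window - nchar(lib$cre_seq)
  lib$oligo_seq <- vapply(seq_len(nrow(lib)), function(r)
    assembleOligo(lib$cre_seq[r], lib$barcode[r],
                  padSequence(lib$pad_len[r], lib$construct_id[r],
                              parts$rs),
                  parts), character(1))
  rownames(lib) <- NULL
  lib[, c("construct_id", "gene", "region_index", "allele_label",
          "variant_ids", "barcode", "pad_len", "cre_seq", "oligo_seq")]
}
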