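#' Read position probability matrices in MEME minimal text format
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix` sections
#' (alphabet ACGT) into [Pwm-class] objects with the given background.
#'
#' @param path path to a MEME minimal format file.
#' @param backgroundGC GC fraction for the scoring background.
#' @return named list of `Pwm` objects.
#' @export
readMeme <- function(path, backgroundGC = 0.36) {
  lines <- readLines(path)
  starts <- grep("^MOTIF\\s", lines)
  if (!length(starts)) stop("no MOTIF blocks in ", path)
  out <- list()
  for (s in starts) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    h <- s
    while (h <= length(lines) &&
           !grepl("letter-probability matrix", lines[h])) h <- h + 1
    if (h > length(lines)) stop("motif ", name, " has no probability matrix")
    rows <- list()
    i <- h + 1
    while (i <= length(lines) &&
           grepl("^\\s*[0-9.eE+-]+(\\s+[0-9.eE+-]+){3}\\s*$", lines[i])) {
      rows[[length(rows) + 1]] <-
        as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]])
      i <- i + 1
    }
    if (!length(rows)) stop("motif ", name, " has an empty matrix")
    out[[name]] <- Pwm(name, do.call(rbind, rows),
                       backgroundGC = backgroundGC)
  }
  out
}

# log2 likelihood-ratio score of a motif placement; ambiguous bases
# contribute 0 (treated as background).
scorePlacement <- function(chars, pwm) {
  logodds <- log2(pwm@prob / matrix(pwm@background, nrow(pwm@prob), 4,
                                    byrow = TRUE))
  idx <- match(chars, c("A", "C", "G", "T"))
  s <- 0
  for (i in seq_along(chars))
    if (!is.na(idx[i])) s <- s + logodds[i, idx[i]]
  s
}

#' Scan a sequence with a position weight matrix
#'
#' Scores every placement of the motif on both strands as the sum over
#' positions of log2(p_motif(base) / p_background(base)), returns the best
#' score and its position, and floors negative best scores to zero (a score
#' of zero means the motif fits no better than the background). Ambiguous
#' bases contribute zero.
#'
#' @param sequence character DNA sequence (length >= motif length).
#' @param pwm a [Pwm-class] object.
#' @return list with `score` (floored at 0), `raw` (unfloored best),
#'   `position` (1-based start of the best placement) and `strand`.
#' @examples
#' m <- Pwm("ex", rbind(c(.64, .12, .12, .12), c(.1, .09, .72, .09)),
#'          pseudocount = 0)
#' pwmScan("AG", m)$score  # 3
#' @export
pwmScan <- function(sequence, pwm) {
  L <- nchar(sequence)
  m <- motifLength(pwm)
  if (L < m) stop("sequence shorter than the motif")
  logodds <- log2(pwm@prob / matrix(pwm@background, m, 4, byrow = TRUE))
  scoreStrand <- function(seqChars) {
    idx <- match(seqChars, c("A", "C", "G", "T"))
    ih <- matrix(0, length(idx), 4)
    ih[cbind(which(!is.na(idx)), idx[!is.na(idx)])] <- 1
    contrib <- ih %*% t(logodds)   # position x motif-position contribution
    vapply(seq_len(L - m + 1), function(o)
      sum(contrib[cbind(o:(o + m - 1), seq_len(m))]), numeric(1))
  }
  fwd <- scoreStrand(strsplit(toupper(sequence), "")[[1]])
  rcChars <- strsplit(revComp(toupper(sequence)), "")[[1]]
  rev <- scoreStrand(rcChars)
  bestF <- which.max(fwd); bestR <- which.max(rev)
  if (fwd[bestF] >= rev[bestR]) {
    raw <- fwd[bestF]; pos <- bestF; strand <- "+"
  } else {
    raw <- rev[bestR]
    pos <- L - (bestR + m - 1) + 1   # map back to forward coordinates
    strand <- "-"
  }
  list(score = max(raw, 0), raw = raw, position = pos, strand = strand)
}

#' Binding-change score of a variant
#'
#' For each motif, the sequences around the variant on the two alleles
#' (typically 30 bp of flank on either side) are scanned and the absolute
#' difference of the best (floored) scores is taken; the annotation is the
#' maximum difference across all motifs, together with the motif attaining
#' it. A signed version (allele1 - allele2 at the maximizing motif) is also
#' reported.
#'
#' @param allele1Context,allele2Context variant-centered sequences of the
#'   two alleles.
#' @param motifs non-empty list of [Pwm-class] objects.
#' @return list with `binding_delta` (>= 0), `best_motif`, `signed_delta`.
#' @export
bindingChangeScore <- function(allele1Context, allele2Context, motifs) {
  if (!length(motifs)) stop("empty motif set")
  deltas <- vapply(motifs, function(m)
    pwmScan(allele1Context, m)$score - pwmScan(allele2Context, m)$score,
    numeric(1))
  best <- which.max(abs(deltas))
  list(binding_delta = abs(deltas[[best]]),
       best_motif = if (!is.null(names(motifs))) names(motifs)[best]
                    else pwmName(motifs[[best]]),
       signed_delta = unname(deltas[best]))
}

#' Extract variant-centered allele contexts from two genomes
#'
#' Convenience helper for [bindingChangeScore()]: takes `flank` bp on
#' either side of the variant from the parent-1 genome and builds the
#' parent-2 context by substituting the alternate allele. Flanks are
#' clipped (with a flag) at contig ends.
#'
#' @param genome `DNAStringSet` of parent-1 contigs.
#' @param variant one-row data.frame (chrom, pos, ref, alt).
#' @param flank flank length (default 30).
#' @return list with `allele1`, `allele2`, `clipped`.
#' @export
variantContexts <- function(genome, variant, flank = 30) {
  chr <- genome[[variant$chrom]]
  lo <- max(1, variant$pos - flank)
  hi <- min(length(chr), variant$pos + nchar(variant$ref) - 1 + flank)
  clipped <- lo > variant$pos - flank ||
    hi < variant$pos + nchar(variant$ref) - 1 + flank
  ctx1 <- as.character(Biostrings::subseq(chr, lo, hi))
  relPos <- variant$pos - lo + 1
  stopifnot(substr(ctx1, relPos, relPos + nchar(variant$ref) - 1) ==
              variant$ref)
  ctx2 <- paste0(substr(ctx1, 1, relPos - 1), variant$alt,
                 substr(ctx1, relPos + nchar(variant$ref), nchar(ctx1)))
  list(allele1 = ctx1, allele2 = ctx2, clipped = clipped)
}

#' Annotate variants with conservation scores
#'
#' SNPs receive the score at their site. InDels receive the mean of the
#' scores at the two sites flanking the InDel span plus any scores at sites
#' within it. Sites absent from the track give NA (for InDels, missing
#' sites are dropped from the mean; all-missing gives NA).
#'
#' @param variants data.frame (chrom, pos, ref, alt, type); InDels are
#'   VCF-style anchored, so the affected span starts at pos + 1.
#' @param track per-base score track: a `GRanges` with a `score` column
#'   (e.g. imported from bedGraph) or a data.frame (chrom, pos, score).
#' @return numeric vector of scores, one per variant.
#' @export
phastconsAnnotate <- function(variants, track) {
  if (is(track, "GRanges")) {
    pos <- unlist(mapply(seq, GenomicRanges::start(track),
                         GenomicRanges::end(track), SIMPLIFY = FALSE))
    reps <- GenomicRanges::width(track)
    track <- data.frame(
      chrom = rep(as.character(GenomicRanges::seqnames(track)), reps),
      pos = pos, score = rep(track$score, reps))
  }
  key <- paste(track$chrom, track$pos)
  lookup <- function(chrom, p) {
    i <- match(paste(chrom, p), key)
    ifelse(is.na(i), NA_real_, track$score[i])
  }
  vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    if (v$type == "SNP") return(lookup(v$chrom, v$pos))
    # anchored InDel: affected span is [pos + 1, pos + nchar(ref) - 1]
    # (empty for insertions); flanks are the sites just outside the span
    inner <- if (nchar(v$ref) > 1) seq(v$pos + 1, v$pos + nchar(v$ref) - 1)
      else integer(0)
    sites <- c(v$pos, inner, v$pos + nchar(v$ref))
    sc <- lookup(v$chrom, sites)
    if (all(is.na(sc))) NA_real_ else mean(sc, na.rm = TRUE)
  }, numeric(1))
}

#' One-way ANOVA of annotation scores across variant groups
#'
#' Tests whether an annotation score differs among groups of variants
#' (e.g. reporter-positive, reporter-negative, and all other intergenic
#' variants).
#'
#' @param scores numeric annotation scores.
#' @param groups group label per score (>= 2 groups with >= 2 members).
#' @return list with `F`, `p`, `df`.
#' @export
scoreGroupAnova <- function(scores, groups) {
  groups <- as.factor(groups)
  ok <- !is.na(scores) & !is.na(groups)
  scores <- scores[ok]; groups <- droplevels(groups[ok])
  if (nlevels(groups) < 2 || any(table(groups) < 2))
    stop("need >= 2 groups with >= 2 members")
  fit <- summary(aov(scores ~ groups))[[1]]
  list(F = fit$`F value`[1], p = fit$`Pr(>F)`[1],
       df = fit$Df[seq_len(2)])
}
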