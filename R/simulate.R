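#' Trajectory parameters for a diauxic-shift expression profile
#'
#' A minimal parametric family for per-gene expression over the timecourse:
#' a four-parameter logistic in time for monotone (increase/decrease)
#' profiles, a difference of two logistics for transient (peak/trough)
#' profiles, and a constant for flat profiles. Time is measured in timepoint
#' indices (0-based); `t50` is the midpoint of the shift response and `slope`
#' its steepness.
#'
#' @param baseline expression rate before the shift (arbitrary units, > 0).
#' @param amplitude signed change realized across the shift; must satisfy
#'   `baseline + min(0, amplitude) > 0`; 0 for `shape = "flat"`.
#' @param t50 midpoint of the response, in timepoint units.
#' @param slope logistic steepness (> 0).
#' @param shape one of `"increase"`, `"decrease"`, `"peak"`, `"trough"`,
#'   `"flat"`.
#' @param width separation (timepoints) of the two logistics for
#'   peak/trough shapes.
#' @return a `trajectoryParams` list.
#' @examples
#' p <- trajectoryParams(10, 20, t50 = 7, slope = 1, shape = "increase")
#' trajectoryMean(p, 0:18)
#' @export
trajectoryParams <- function(baseline, amplitude, t50, slope,
                             shape = c("increase", "decrease", "peak",
                                       "trough", "flat"),
                             width = 4) {
  shape <- match.arg(shape)
  if (baseline <= 0) stop("'baseline' must be > 0")
  if (slope <= 0) stop("'slope' must be > 0")
  if (shape == "flat") amplitude <- 0
  if (shape == "increase" && amplitude < 0) stop("increase needs amplitude >= 0")
  if (shape == "decrease" && amplitude > 0) stop("decrease needs amplitude <= 0")
  if (shape == "peak" && amplitude < 0) stop("peak needs amplitude >= 0")
  if (shape == "trough" && amplitude > 0) stop("trough needs amplitude <= 0")
  structure(list(baseline = baseline, amplitude = amplitude, t50 = t50,
                 slope = slope, shape = shape, width = width),
            class = "trajectoryParams")
}

#' Mean expression of a trajectory at given times
#'
#' @param params a [trajectoryParams()] object.
#' @param t numeric times (timepoint indices).
#' @return numeric vector of strictly positive mean expression values.
#' @export
trajectoryMean <- function(params, t) {
  stopifnot(inherits(params, "trajectoryParams"))
  mu <- switch(params$shape,
    flat = rep(params$baseline, length(t)),
    increase = ,
    decrease = params$baseline +
      params$amplitude * plogis(params$slope * (t - params$t50)),
    peak = ,
    trough = params$baseline + params$amplitude *
      (plogis(params$slope * (t - params$t50)) -
       plogis(params$slope * (t - params$t50 - params$width)))
  )
  pmax(mu, 1e-9)
}

#' ASE effect description
#'
#' The transformation applied to allele 2's trajectory relative to allele 1:
#' `level` multiplies the whole curve by `2^magnitude` (a constant log2
#' allelic imbalance), `delay` shifts `t50` by `magnitude` timepoints, `rate`
#' multiplies the logistic slope by `magnitude`, and `condition` multiplies
#' the shift amplitude by `2^magnitude` (an imbalance present in one
#' environment only). `none` leaves the curve unchanged.
#'
#' @param kind one of `"none"`, `"level"`, `"delay"`, `"rate"`,
#'   `"condition"`.
#' @param magnitude effect size (log2 ratio for level/condition, timepoints
#'   for delay, slope multiplier for rate); forced to 0 for `kind = "none"`.
#' @return an `aseEffect` list.
#' @export
aseEffect <- function(kind = c("none", "level", "delay", "rate", "condition"),
                      magnitude = 0) {
  kind <- match.arg(kind)
  if (kind == "none") magnitude <- 0
  if (kind == "rate" && magnitude <= 0)
    stop("rate effects need a positive slope multiplier")
  structure(list(kind = kind, magnitude = magnitude), class = "aseEffect")
}

# Apply an ASE effect to trajectory params; returns list(params2, scale2)
# where allele 2's mean curve is scale2 * trajectoryMean(params2, t).
applyAseEffect <- function(params, effect) {
  p2 <- params
  s2 <- 1
  switch(effect$kind,
    none = NULL,
    level = { s2 <- 2^effect$magnitude },
    delay = { p2$t50 <- p2$t50 + effect$magnitude },
    rate = { p2$slope <- p2$slope * effect$magnitude },
    condition = { p2$amplitude <- p2$amplitude * 2^effect$magnitude }
  )
  list(params = p2, scale = s2)
}

#' Noise-free allele mean curves under an ASE effect
#'
#' @param params allele 1 [trajectoryParams()].
#' @param effect an [aseEffect()].
#' @param t timepoint indices.
#' @return list with components `mu1` and `mu2` (unscaled mean curves).
#' @export
aseAlleleMeans <- function(params, effect, t) {
  tr <- applyAseEffect(params, effect)
  list(mu1 = trajectoryMean(params, t),
       mu2 = tr$scale * trajectoryMean(tr$params, t))
}

# Draw random trajectory parameters emulating the cluster shapes of a
# glucose-depletion timecourse.
randomTrajectory <- function(nTimepoints, shiftIndex, shape = NULL) {
  shapes <- c("increase", "decrease", "peak", "trough", "flat")
  if (is.null(shape))
    shape <- sample(shapes, 1, prob = c(0.3, 0.3, 0.125, 0.125, 0.15))
  baseline <- rlnorm(1, meanlog = log(10), sdlog = 0.6)
  relAmp <- runif(1, 0.5, 0.9)
  amplitude <- switch(shape,
    increase = relAmp * baseline * runif(1, 1, 3),
    decrease = -relAmp * baseline,
    peak = relAmp * baseline * runif(1, 1, 3),
    trough = -relAmp * baseline,
    flat = 0)
  trajectoryParams(baseline, amplitude,
                   t50 = shiftIndex + runif(1, -1.5, 1.5),
                   slope = runif(1, 0.8, 2), shape = shape)
}

#' Simulate an allele-resolved count timecourse with known ASE effects
#'
#' Generates per-gene, per-timepoint read counts for two alleles of a hybrid.
#' Allele 1 follows a random trajectory from the diauxic-shift family; allele
#' 2's mean curve is allele 1's transformed by the gene's [aseEffect()].
#' Counts are negative binomial around the allele means (variance
#' `mu + dispersion * mu^2`; `dispersion = 0` gives Poisson), with
#' per-timepoint library sizes drawn lognormal (sdlog 0.2) around `depth`.
#'
#' Defaults mirror the structure of a 19-timepoint diauxic-shift ASE study
#' of ~4703 genes at 2-3 million allele reads per timepoint (roughly 600
#' reads per gene per timepoint).
#'
#' @param nGenes number of genes.
#' @param nTimepoints number of timepoints (>= 4; default 19).
#' @param depth mean total allele reads per gene per timepoint (> 0).
#' @param dispersion negative-binomial overdispersion (>= 0).
#' @param effectMix named fractions of genes carrying each effect kind
#'   (`level`, `delay`, `rate`, `condition`); must sum to <= 1, the
#'   remainder being effect-free genes.
#' @param magnitudes named list of effect magnitudes used for affected
#'   genes; the direction (which allele is stronger, earlier or steeper) is
#'   randomized per gene so that effects are symmetric between alleles.
#' @param shiftIndex timepoint index of glucose depletion (default 7).
#' @param shape optionally force one trajectory shape for all genes (e.g.
#'   `"flat"` for an exchangeable null in which the timepoints carry no
#'   expression trajectory); by default shapes are drawn per gene.
#' @param seed root seed; all randomness derives from it.
#' @param hybrid label stored in the returned object.
#' @return list with `counts` (an [AlleleCounts-class]), `truth` (data.frame
#'   gene/kind/magnitude/shape/baseline/amplitude/t50/slope) and `libSize`
#'   (per-timepoint library factors).
#' @examples
#' sim <- simulateAseCounts(50, depth = 200, effectMix = c(level = 0.2),
#'                          seed = 1)
#' table(sim$truth$kind)
#' @export
simulateAseCounts <- function(nGenes, nTimepoints = 19, depth = 600,
                              dispersion = 0.01,
                              effectMix = c(level = 0, delay = 0, rate = 0,
                                            condition = 0),
                              magnitudes = list(level = 1, delay = 2,
                                                rate = 3, condition = 1.5),
                              shiftIndex = 7, shape = NULL, seed = 1,
                              hybrid = "sim") {
  if (depth <= 0) stop("'depth' must be positive")
  if (nTimepoints < 4) stop("at least 4 timepoints are required")
  kinds <- c("level", "delay", "rate", "condition")
  mix <- setNames(rep(0, 4), kinds)
  mix[names(effectMix)] <- effectMix
  if (any(mix < 0) || sum(mix) > 1)
    stop("effect fractions must be non-negative and sum to <= 1")
  withSeed(childSeed(seed, "ase_counts"), {
    t <- seq_len(nTimepoints) - 1
    nEff <- floor(mix * nGenes)
    kind <- rep("none", nGenes)
    if (sum(nEff) > 0)
      kind[seq_len(sum(nEff))] <- rep(kinds, nEff)
    libSize <- exp(rnorm(nTimepoints, sd = 0.2) - 0.02)
    ref <- alt <- matrix(0L, nGenes, nTimepoints,
                         dimnames = list(sprintf("gene%04d", seq_len(nGenes)),
                                         paste0("t", t)))
    truth <- vector("list", nGenes)
    for (g in seq_len(nGenes)) {
      # dynamics effects need a responsive (non-flat) trajectory to act on
      shp <- if (!is.null(shape)) shape
      else if (kind[g] %in% c("delay", "rate", "condition"))
        sample(c("increase", "decrease", "peak", "trough"), 1,
               prob = c(0.35, 0.35, 0.15, 0.15)) else NULL
      params <- randomTrajectory(nTimepoints, shiftIndex, shape = shp)
      # the disfavoured/slower allele is random, so effects are symmetric
      # between alleles and do not bias the joint normalization
      mag <- if (kind[g] == "none") 0 else magnitudes[[kind[g]]]
      if (kind[g] %in% c("level", "condition", "delay") && runif(1) < 0.5)
        mag <- -mag
      if (kind[g] == "rate" && runif(1) < 0.5)
        mag <- 1 / mag
      eff <- aseEffect(kind[g], mag)
      mus <- aseAlleleMeans(params, eff, t)
      sc <- depth / mean(mus$mu1 + mus$mu2)
      ref[g, ] <- rcounts(nTimepoints, sc * mus$mu1 * libSize, dispersion)
      alt[g, ] <- rcounts(nTimepoints, sc * mus$mu2 * libSize, dispersion)
      truth[[g]] <- data.frame(gene = rownames(ref)[g], kind = kind[g],
                               magnitude = eff$magnitude,
                               shape = params$shape,
                               baseline = params$baseline,
                               amplitude = params$amplitude,
                               t50 = params$t50, slope = params$slope)
    }
    list(counts = AlleleCounts(ref, alt, timepoints = t, hybrid = hybrid),
         truth = do.call(rbind, truth), libSize = libSize)
  })
}

#' Simulate CRE-seq DNA and RNA barcode counts
#'
#' Per barcode, a library (DNA) abundance is drawn once (lognormal around
#' `dnaDepth`) and held constant across samples up to counting noise; the RNA
#' mean at each timepoint is the DNA abundance times the construct's
#' expression. Counts are negative binomial with the given dispersion.
#'
#' @param manifest data.frame with columns `construct_id` and `barcode`
#'   (one row per barcode; every construct needs >= 1 barcode).
#' @param effects either a named list of [trajectoryParams()] keyed by
#'   construct id, or a numeric matrix of expression values
#'   (constructs x timepoints, rownames = construct ids). Construct ids not
#'   present in the manifest raise an error.
#' @param nTimepoints number of RNA samples (ignored when `effects` is a
#'   matrix).
#' @param dnaDepth mean DNA reads per barcode.
#' @param dispersion negative-binomial overdispersion (0 = Poisson).
#' @param nDnaSamples number of DNA samples (default 2: first and last
#'   timepoint).
#' @param seed root seed.
#' @param exact if TRUE, return the expected means instead of random counts
#'   (useful for noise-free checks).
#' @return a [CreCounts-class] object; the generating expression matrix is
#'   attached as `metadata` field `expression`.
#' @export
simulateCreCounts <- function(manifest, effects, nTimepoints = 19,
                              dnaDepth = 1000, dispersion = 0.05,
                              nDnaSamples = 2, seed = 1, exact = FALSE) {
  manifest <- as.data.frame(manifest)
  stopifnot(all(c("construct_id", "barcode") %in% colnames(manifest)))
  if (anyDuplicated(manifest$barcode))
    stop("barcodes must be unique in the manifest")
  ids <- unique(manifest$construct_id)
  if (is.matrix(effects)) {
    if (!all(rownames(effects) %in% ids) || !all(ids %in% rownames(effects)))
      stop("expression matrix rows must match manifest construct ids")
    expr <- effects
    nTimepoints <- ncol(expr)
  } else {
    if (!all(names(effects) %in% ids))
      stop("unknown construct id in 'effects'")
    if (!all(ids %in% names(effects)))
      stop("every construct needs an expression effect")
    t <- seq_len(nTimepoints) - 1
    expr <- t(vapply(effects, trajectoryMean, numeric(nTimepoints), t = t))
    rownames(expr) <- names(effects)
  }
  withSeed(childSeed(seed, "cre_counts"), {
    nb <- nrow(manifest)
    abund <- rlnorm(nb, meanlog = log(dnaDepth) - 0.125, sdlog = 0.5)
    rnaMu <- abund * expr[manifest$construct_id, , drop = FALSE]
    dnaMu <- matrix(abund, nb, nDnaSamples)
    if (exact) {
      rna <- rnaMu; dna <- dnaMu
    } else {
      rna <- matrix(rcounts(length(rnaMu), as.vector(rnaMu), dispersion),
                    nb, nTimepoints)
      dna <- matrix(rcounts(length(dnaMu), as.vector(dnaMu), dispersion),
                    nb, nDnaSamples)
    }
    rownames(rna) <- rownames(dna) <- manifest$barcode
    colnames(rna) <- paste0("rna_t", seq_len(nTimepoints) - 1)
    colnames(dna) <- paste0("dna_", seq_len(nDnaSamples))
    out <- CreCounts(rna, dna, manifest, time = seq_len(nTimepoints) - 1)
    attr(out, "expression") <- expr
    out
  })
}

#' Simulate a two-haplotype genome fixture with genes, TSSs and variants
#'
#' Builds a single contig of alternating intergenic and CDS blocks, annotates
#' genes (with a `tss` attribute) and derives a second haplotype by placing
#' SNPs and InDels at the given per-bp rates. Variants are reported VCF-style
#' (1-based, anchored InDels) on haplotype 1 coordinates.
#'
#' @param nGenes number of genes.
#' @param intergenicLen intergenic block length (bp); must accommodate the
#'   promoter windows you intend to design.
#' @param cdsLen CDS length per gene (bp).
#' @param tssOffset distance of the TSS upstream of the CDS start (bp).
#' @param variantRates named per-bp rates, `snp` and `indel`, each in
#'   \[0, 1\].
#' @param strand either a single strand for all genes or a vector recycled
#'   across genes.
#' @param seed root seed.
#' @param dir if non-NULL, write `genome.fa`, `genes.gff3` and
#'   `variants.tsv` into this directory.
#' @return list with `genome` (DNAStringSet: contig plus its `_alt`
#'   haplotype), `annotation` (GRanges of gene and CDS features),
#'   `tss` (data.frame gene/chrom/pos/strand, 1-based), `variants`
#'   (data.frame chrom/pos/ref/alt/type) and any file paths written.
#' @export
simulateGenomeFixture <- function(nGenes, intergenicLen = 600, cdsLen = 300,
                                  tssOffset = 30,
                                  variantRates = c(snp = 0.01,
                                                   indel = 0.002),
                                  strand = "+", seed = 1, dir = NULL) {
  if (any(variantRates < 0) || any(variantRates > 1))
    stop("variant rates must lie in [0, 1]")
  if (intergenicLen < tssOffset)
    stop("'intergenicLen' must exceed 'tssOffset'")
  strand <- rep_len(strand, nGenes)
  withSeed(childSeed(seed, "genome_fixture"), {
    unit <- intergenicLen + cdsLen
    total <- nGenes * unit + intergenicLen
    bases <- c("A", "C", "G", "T")
    hap1 <- sample(bases, total, replace = TRUE)
    genes <- lapply(seq_len(nGenes), function(i) {
      cdsStart <- (i - 1) * unit + intergenicLen + 1
      cdsEnd <- cdsStart + cdsLen - 1
      if (strand[i] == "+") tss <- cdsStart - tssOffset
      else tss <- cdsEnd + tssOffset
      data.frame(gene = sprintf("gene%03d", i), start = cdsStart,
                 end = cdsEnd, strand = strand[i], tss = tss)
    })
    genes <- do.call(rbind, genes)

    # place variants in a single left-to-right pass so InDels never overlap
    vr <- c(snp = 0, indel = 0)
    vr[names(variantRates)] <- variantRates
    variants <- list()
    pos <- 2  # keep position 1 free as a potential anchor
    while (pos < total - 5) {
      u <- runif(1)
      if (u < vr["snp"]) {
        refb <- hap1[pos]
        altb <- sample(setdiff(bases, refb), 1)
        variants[[length(variants) + 1]] <-
          data.frame(chrom = "chrI", pos = pos, ref = refb, alt = altb,
                     type = "SNP")
        pos <- pos + 1
      } else if (u < vr["snp"] + vr["indel"]) {
        len <- sample(1:4, 1)
        anchor <- hap1[pos - 1]
        if (runif(1) < 0.5) {  # deletion of `len` bases after the anchor
          variants[[length(variants) + 1]] <-
            data.frame(chrom = "chrI", pos = pos - 1,
                       ref = paste0(anchor,
                                    paste(hap1[pos:(pos + len - 1)],
                                          collapse = "")),
                       alt = anchor, type = "DEL")
          pos <- pos + len + 1
        } else {               # insertion after the anchor
          ins <- paste(sample(bases, len, replace = TRUE), collapse = "")
          variants[[length(variants) + 1]] <-
            data.frame(chrom = "chrI", pos = pos - 1, ref = anchor,
                       alt = paste0(anchor, ins), type = "INS")
          pos <- pos + 2
        }
      } else pos <- pos + 1
    }
    variants <- if (length(variants)) do.call(rbind, variants)
      else data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      type = character())

    hap1seq <- paste(hap1, collapse = "")
    hap2seq <- applyVariants(hap1seq, variants)
    genome <- Biostrings::DNAStringSet(c(chrI = hap1seq,
                                         chrI_alt = hap2seq))

    gr <- GenomicRanges::GRanges("chrI",
            IRanges::IRanges(genes$start, genes$end),
            strand = genes$strand)
    gr$type <- "CDS"
    gr$ID <- genes$gene
    gr$tss <- genes$tss
    gr$phase <- 0L
    ann <- c(gr, gr)
    ann$type[seq_len(nGenes)] <- "gene"
    ann$phase[seq_len(nGenes)] <- NA_integer_
    ann <- sort(ann)

    out <- list(genome = genome, annotation = ann,
                tss = data.frame(gene = genes$gene, chrom = "chrI",
                                 pos = genes$tss, strand = genes$strand),
                variants = variants)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      out$files <- c(
        fasta = writeGenomeFasta(genome, file.path(dir, "genome.fa")),
        gff = writeGff3(ann, file.path(dir, "genes.gff3")),
        variants = writeVariants(variants, file.path(dir, "variants.tsv")))
    }
    out
  })
}

# Apply VCF-style variants (1-based, anchored) to a sequence string.
applyVariants <- function(seq, variants) {
  if (nrow(variants) == 0) return(seq)
  v <- variants[order(variants$pos, decreasing = TRUE), , drop = FALSE]
  for (i in seq_len(nrow(v))) {
    p <- v$pos[i]
    stopifnot(substr(seq, p, p + nchar(v$ref[i]) - 1) == v$ref[i])
    seq <- paste0(substr(seq, 1, p - 1), v$alt[i],
                  substr(seq, p + nchar(v$ref[i]), nchar(seq)))
  }
  seq
}

#' Simulate per-gene variant burden and ASE status under a logistic model
#'
#' ASE status is drawn Bernoulli with log-odds `b0 + b1 * x`, where `x` is
#' the per-gene variant count; used for parameter recovery of the
#' association stage.
#'
#' @param nGenes number of genes.
#' @param burdenLambda Poisson mean of the variant count `x`, or pass a
#'   numeric vector `x` directly.
#' @param b0,b1 logistic intercept and per-variant coefficient.
#' @param x optional explicit variant counts, overriding `burdenLambda`.
#' @param seed root seed.
#' @return data.frame with columns gene, x, prob, ase (logical).
#' @export
simulateVariantBurden <- function(nGenes, burdenLambda = 2, b0 = -1,
                                  b1 = 0.5, x = NULL, seed = 1) {
  withSeed(childSeed(seed, "variant_burden"), {
    if (is.null(x)) x <- rpois(nGenes, burdenLambda)
    stopifnot(length(x) == nGenes)
    p <- plogis(b0 + b1 * x)
    data.frame(gene = sprintf("gene%05d", seq_len(nGenes)), x = x,
               prob = p, ase = runif(nGenes) < p)
  })
}
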