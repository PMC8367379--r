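# Shared fixture builders; everything is generated in code at test time.

# An AlleleCounts object with exact (non-random) counts.
makeCounts <- function(ref, alt, ...) {
  AlleleCounts(as.matrix(ref), as.matrix(alt), ...)
}

# Null counts: both alleles Poisson around depth/2, no ASE.
nullCounts <- function(nGenes, nTimepoints = 19, depth = 600, seed = 1,
                       dispersion = 0.01) {
  simulateAseCounts(nGenes, nTimepoints = nTimepoints, depth = depth,
                    dispersion = dispersion, seed = seed)$counts
}

# Independent textbook Durbin-Watson statistic of a series around its mean
# (via lmtest on an intercept-only fit), used as the w = 1 oracle.
classicalDw <- function(y) {
  unname(lmtest::dwtest(lm(y ~ 1))$statistic)
}

# Brute-force PWM best score: enumerate every offset on both strands.
bruteForcePwmBest <- function(sequence, pwm) {
  prob <- pwmProb(pwm)
  bg <- pwm@background
  m <- nrow(prob)
  score1 <- function(s) {
    best <- -Inf
    chars <- strsplit(s, "")[[1]]
    for (o in seq_len(nchar(s) - m + 1)) {
      sc <- 0
      for (j in seq_len(m)) {
        b <- chars[o + j - 1]
        if (b %in% c("A", "C", "G", "T"))
          sc <- sc + log2(prob[j, b] / bg[[b]])
      }
      best <- max(best, sc)
    }
    best
  }
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(sequence)))
  max(0, score1(sequence), score1(rc))
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A minimal two-allele CRE manifest with nBarcodes per construct.
toyManifest <- function(constructs, nBarcodes = 4, seed = 1) {
  bcs <- generateBarcodes(length(constructs) * nBarcodes, seed = seed)
  data.frame(construct_id = rep(constructs, each = nBarcodes),
             gene = "geneX", region_index = 0,
             allele_label = rep(constructs, each = nBarcodes),
             barcode = bcs)
}
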