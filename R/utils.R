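# Internal helpers shared across modules.

# Derive a child RNG seed from a root seed and a fixed generator label, so
# adding a generator never perturbs the stream of another. Plain 32-bit-safe
# polynomial string hash folded into [0, 2^31 - 2].
childSeed <- function(seed, label) {
  stopifnot(length(seed) == 1, is.finite(seed))
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 + h) %% 2147483647)
}

# Evaluate expr under a local, restored RNG state with the given seed.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# Negative binomial draws parameterized by mean mu and dispersion alpha
# (variance = mu + alpha mu^2); alpha = 0 degenerates to Poisson.
rcounts <- function(n, mu, dispersion) {
  if (dispersion < 0) stop("'dispersion' must be >= 0")
  if (dispersion == 0) rpois(n, lambda = mu)
  else rnbinom(n, mu = mu, size = 1 / dispersion)
}

# Reverse complement for plain character DNA (vectorized).
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# For each of `seqs`, does any of `sites` (or its reverse complement)
# occur in it?
containsSite <- function(seqs, sites) {
  hit <- logical(length(seqs))
  for (site in sites)
    hit <- hit | grepl(site, seqs, fixed = TRUE) |
      grepl(revComp(site), seqs, fixed = TRUE)
  hit
}

# Format numbers for TSV output with 6 significant digits (reproducible diffs).
fmtNum <- function(x) ifelse(is.na(x), "NA", formatC(x, digits = 6,
                                                     format = "g"))
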