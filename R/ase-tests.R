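#' Weighted test for allele-specific expression levels
#'
#' Fits the weighted intercept model f_i = 0.5 + beta0 + e_i by weighted
#' least squares (weights w_i = total reads), so beta0 is the read-weighted
#' mean deviation of the reference-allele frequency from 0.5:
#' beta0 = sum(w (f - 0.5)) / sum(w). The p-value is a two-sided t test of
#' beta0 = 0 using the weighted residual variance with T - 1 degrees of
#' freedom (T = number of defined timepoints).
#'
#' @param f reference-allele frequencies per timepoint (NA = undefined).
#' @param w non-negative weights (total raw reads per timepoint).
#' @return list with `beta0`, `se`, `p`, `df` and logical `untestable`
#'   (fewer than 2 defined timepoints).
#' @examples
#' testAseLevels(c(0.6, 0.7), c(100, 300))$beta0  # 0.175
#' @export
testAseLevels <- function(f, w) {
  stopifnot(length(f) == length(w), all(w >= 0, na.rm = TRUE))
  ok <- !is.na(f) & !is.na(w) & w > 0
  n <- sum(ok)
  if (n < 2)
    return(list(beta0 = NA_real_, se = NA_real_, p = NA_real_,
                df = NA_integer_, untestable = TRUE))
  f <- f[ok]; w <- w[ok]
  beta0 <- sum(w * (f - 0.5)) / sum(w)
  e <- (f - 0.5) - beta0
  s2 <- sum(w * e^2) / (n - 1)
  se <- sqrt(s2 / sum(w))
  p <- if (se == 0) as.numeric(beta0 == 0) else
    2 * pt(-abs(beta0 / se), df = n - 1)
  list(beta0 = beta0, se = se, p = p, df = n - 1L, untestable = FALSE)
}

#' Weighted Durbin-Watson statistic
#'
#' The dynamics statistic on weighted residuals u_i = w_i e_i taken in
#' timepoint order: sum over i of (u_(i+1) - u_i)^2 divided by sum of u_i^2.
#' With unit weights this is the classical Durbin-Watson statistic of the
#' residual series. When all weighted residuals are zero the statistic is
#' defined as 2 (the no-autocorrelation value).
#'
#' @param e residuals of the levels model, in timepoint order.
#' @param w weights (same length); defaults to unit weights.
#' @return the statistic (>= 0).
#' @export
weightedDwStat <- function(e, w = rep(1, length(e))) {
  stopifnot(length(e) == length(w))
  u <- w * e
  den <- sum(u^2)
  if (den == 0) return(2)
  sum(diff(u)^2) / den
}

#' Weighted Durbin-Watson test for allele-specific expression dynamics
#'
#' Computes the weighted Durbin-Watson statistic on the residuals of the
#' levels model ([testAseLevels()]) and a permutation p-value over random
#' reorderings of the timepoints: the two-sided fraction of permutations
#' whose statistic is at least as far from the permutation mean as the
#' observed one, smoothed as (b + 1) / (nPerm + 1). Exchangeability of the
#' timepoints under the null (constant allelic ratio) makes this exact up to
#' Monte-Carlo error.
#'
#' With `pMethod = "normal"` the permutation draws are instead summarized
#' by their mean and standard deviation and the p-value is the two-sided
#' normal tail probability of the observed statistic; this removes the
#' 1 / (nPerm + 1) granularity of the permutation p-value (useful when BH
#' adjustment over few genes needs p-values below the permutation floor)
#' at the price of a tail approximation.
#'
#' @param f,w as in [testAseLevels()]; at least 4 defined timepoints.
#' @param nPerm number of permutations (default 1000).
#' @param seed seed for the permutation draws.
#' @param pMethod `"permutation"` (exact, granular) or `"normal"`
#'   (approximate, continuous).
#' @return list with `dw`, `p`, `nPerm` and logical `untestable`.
#' @export
testAseDynamics <- function(f, w, nPerm = 1000, seed = 1,
                            pMethod = c("permutation", "normal")) {
  pMethod <- match.arg(pMethod)
  ok <- !is.na(f) & !is.na(w) & w > 0
  n <- sum(ok)
  if (n < 4)
    return(list(dw = NA_real_, p = NA_real_, nPerm = nPerm,
                untestable = TRUE))
  f <- f[ok]; w <- w[ok]
  lev <- testAseLevels(f, w)
  e <- (f - 0.5) - lev$beta0
  u <- w * e
  if (sum(u^2) == 0)
    return(list(dw = 2, p = 1, nPerm = nPerm, untestable = FALSE))
  dw <- weightedDwStat(e, w)
  dwp <- withSeed(childSeed(seed, "dw_perm"), {
    vapply(seq_len(nPerm), function(i) {
      up <- u[sample.int(n)]
      sum(diff(up)^2) / sum(up^2)
    }, numeric(1))
  })
  center <- mean(dwp)
  p <- if (pMethod == "normal")
    2 * pnorm(-abs(dw - center) / sd(dwp))
  else
    (1 + sum(abs(dwp - center) >= abs(dw - center))) / (nPerm + 1)
  list(dw = dw, p = p, nPerm = nPerm, untestable = FALSE)
}

# Vectorized dynamics test over a gene x timepoint frequency matrix with no
# undefined entries. Each gene gets its own permutation stream: per
# iteration, one fresh random ordering per gene is produced by sorting
# random keys within rows (a single two-key order() call), so per-gene
# p-values are independent and marginally uniform under the null.
# Returns data.frame(dw, p).
aseDynamicsBatch <- function(F, W, nPerm = 1000, seed = 1,
                             pMethod = "permutation") {
  T <- ncol(F)
  n <- nrow(F)
  beta0 <- rowSums(W * (F - 0.5)) / rowSums(W)
  U <- W * ((F - 0.5) - beta0)
  den <- rowSums(U^2)
  dw <- rep(2, n)
  nz <- den > 0
  dw[nz] <- rowSums((U[, -1, drop = FALSE] -
                     U[, -T, drop = FALSE])^2)[nz] / den[nz]
  dwp <- matrix(0, n, nPerm)
  rowIdx <- rep(seq_len(n), times = T)   # row of each column-major cell
  rowRep <- rep(seq_len(n), each = T)    # rows after sorting by row
  withSeed(childSeed(seed, "dw_perm_batch"), {
    for (k in seq_len(nPerm)) {
      o <- order(rowIdx, runif(n * T))
      colOrd <- ((o - 1L) %/% n) + 1L    # per row: columns in random order
      Up <- matrix(U[cbind(rowRep, colOrd)], n, T, byrow = TRUE)
      num <- rowSums((Up[, -1, drop = FALSE] - Up[, -T, drop = FALSE])^2)
      dwp[, k] <- ifelse(nz, num / den, 2)
    }
  })
  center <- rowMeans(dwp)
  if (pMethod == "normal") {
    sdp <- apply(dwp, 1, sd)
    p <- 2 * pnorm(-abs(dw - center) / sdp)
  } else {
    b <- rowSums(abs(dwp - center) >= abs(dw - center))
    p <- (1 + b) / (nPerm + 1)
  }
  p[!nz] <- 1
  data.frame(dw = dw, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Validated thin wrapper over `p.adjust(method = "BH")` (step-up false
#' discovery rate control).
#'
#' @param p p-values in \[0, 1\] (NA allowed).
#' @return adjusted values of the same length.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Full ASE testing pipeline
#'
#' Filters genes on raw coverage, normalizes counts by median-of-ratios,
#' computes reference-allele frequency series, and runs the weighted levels
#' test and the weighted Durbin-Watson dynamics test for every gene, with
#' Benjamini-Hochberg adjustment of both p-value families.
#'
#' @param x an [AlleleCounts-class] object of raw counts.
#' @param nPerm permutations for the dynamics p-value.
#' @param seed seed for the permutation draws.
#' @param filter apply [filterGenes()] first (default TRUE).
#' @param minDefinedDynamics minimum defined timepoints for the dynamics
#'   test (default 4).
#' @param pMethod dynamics p-value method, see [testAseDynamics()].
#' @return data.frame with one row per tested gene: beta0, se, p_levels,
#'   q_levels, dw, p_dyn, q_dyn, n_defined and the untestable flags.
#' @export
aseTest <- function(x, nPerm = 1000, seed = 1, filter = TRUE,
                    minDefinedDynamics = 4,
                    pMethod = c("permutation", "normal")) {
  pMethod <- match.arg(pMethod)
  if (filter) x <- x[filterGenes(x), ]
  if (nrow(x) == 0) stop("no genes left after filtering")
  af <- alleleFrequency(x)
  F <- af$f; W <- af$w
  nDef <- rowSums(!is.na(F) & W > 0)

  # vectorized levels test
  Fd <- F; Fd[W == 0] <- NA
  Wd <- W * !is.na(Fd)
  sw <- rowSums(Wd, na.rm = TRUE)
  beta0 <- rowSums(Wd * (Fd - 0.5), na.rm = TRUE) / sw
  E <- (Fd - 0.5) - beta0
  s2 <- rowSums(Wd * E^2, na.rm = TRUE) / pmax(nDef - 1, 1)
  se <- sqrt(s2 / sw)
  tstat <- beta0 / se
  pLev <- 2 * pt(-abs(tstat), df = nDef - 1)
  pLev[se == 0] <- as.numeric(beta0[se == 0] == 0)
  lvUntest <- nDef < 2
  beta0[lvUntest] <- se[lvUntest] <- pLev[lvUntest] <- NA

  # dynamics: batch the fully-defined genes, loop the rest
  dw <- pDyn <- rep(NA_real_, nrow(x))
  full <- nDef == ncol(x)
  if (any(full)) {
    bat <- aseDynamicsBatch(F[full, , drop = FALSE],
                            W[full, , drop = FALSE], nPerm, seed, pMethod)
    dw[full] <- bat$dw
    pDyn[full] <- bat$p
  }
  for (g in which(!full & nDef >= minDefinedDynamics)) {
    r <- testAseDynamics(F[g, ], W[g, ], nPerm, seed, pMethod)
    dw[g] <- r$dw; pDyn[g] <- r$p
  }
  data.frame(gene = rownames(x), beta0 = beta0, se = se,
             p_levels = pLev, q_levels = bhAdjust(pLev),
             dw = dw, p_dyn = pDyn, q_dyn = bhAdjust(pDyn),
             n_defined = nDef, untestable_levels = lvUntest,
             untestable_dyn = nDef < minDefinedDynamics,
             row.names = NULL)
}

#' Permutation null for the levels test
#'
#' For each permutation replicate, allele labels are swapped with
#' probability 0.5 independently for every gene and timepoint, counts are
#' re-normalized, the levels test is re-run and the number of genes with
#' BH-adjusted values below `fdr` is recorded. This validates the false
#' discovery cutoff on data with the allelic signal destroyed but depth and
#' totals preserved.
#'
#' @param x a filtered [AlleleCounts-class] object.
#' @param nPerm number of permutation replicates (default 10).
#' @param seed seed.
#' @param fdr discovery cutoff on the BH-adjusted values (default 0.01).
#' @return integer vector of per-replicate discovery counts (length
#'   `nPerm`; empty for `nPerm = 0`).
#' @export
permutationNullLevels <- function(x, nPerm = 10, seed = 1, fdr = 0.01) {
  if (nPerm == 0) return(integer(0))
  ref <- refCounts(x); alt <- altCounts(x)
  vapply(seq_len(nPerm), function(k) {
    swap <- withSeed(childSeed(seed, paste0("lev_null_", k)),
                     matrix(runif(length(ref)) < 0.5, nrow(ref)))
    ref2 <- ifelse(swap, alt, ref)
    alt2 <- ifelse(swap, ref, alt)
    xp <- AlleleCounts(ref2, alt2, timepoints = samplingTimes(x),
                       hybrid = hybridName(x))
    af <- alleleFrequency(xp)
    res <- vapply(seq_len(nrow(af$f)), function(g)
      testAseLevels(af$f[g, ], af$w[g, ])$p, numeric(1))
    sum(bhAdjust(res) < fdr, na.rm = TRUE)
  }, integer(1))
}

#' Permutation null for the dynamics test
#'
#' For each replicate, one random reordering of the timepoint labels is
#' applied to all genes (keeping allele pairs together), the dynamics test
#' is re-run with `nInnerPerm` permutation draws, and discoveries at
#' BH-adjusted values below `fdr` are counted.
#'
#' @inheritParams permutationNullLevels
#' @param nInnerPerm permutations for each replicate's dynamics p-values.
#' @param orderings optional list of explicit timepoint orderings (one per
#'   replicate), overriding the random draws; an identity ordering
#'   reproduces the unpermuted analysis.
#' @return integer vector of per-replicate discovery counts.
#' @export
permutationNullDynamics <- function(x, nPerm = 10, seed = 1, fdr = 0.01,
                                    nInnerPerm = 1000, orderings = NULL) {
  if (nPerm == 0) return(integer(0))
  af <- alleleFrequency(x)
  T <- ncol(x)
  vapply(seq_len(nPerm), function(k) {
    ord <- if (!is.null(orderings)) orderings[[k]] else
      withSeed(childSeed(seed, paste0("dyn_null_", k)), sample.int(T))
    F <- af$f[, ord, drop = FALSE]
    W <- af$w[, ord, drop = FALSE]
    nDef <- rowSums(!is.na(F) & W > 0)
    p <- rep(NA_real_, nrow(F))
    full <- nDef == T
    if (any(full))
      p[full] <- aseDynamicsBatch(F[full, , drop = FALSE],
                                  W[full, , drop = FALSE],
                                  nInnerPerm, seed = childSeed(seed, "inner"))$p
    for (g in which(!full & nDef >= 4))
      p[g] <- testAseDynamics(F[g, ], W[g, ], nInnerPerm,
                              seed = childSeed(seed, "inner"))$p
    sum(bhAdjust(p) < fdr, na.rm = TRUE)
  }, integer(1))
}
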