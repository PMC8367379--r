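test_that("median-of-ratios matches the hand-computed oracle", {
  m <- cbind(c1 = c(10, 30, 50), c2 = c(20, 60, 100))
  sf <- medianOfRatios(m)
  expect_equal(unname(sf), c(sqrt(0.5), sqrt(2)), tolerance = 1e-12)
  norm <- sweep(m, 2, sf, "/")
  expect_equal(norm[, 1], norm[, 2])
  # identical columns: all size factors 1
  expect_equal(unname(medianOfRatios(cbind(c(5, 9), c(5, 9)))), c(1, 1))
  # size factors are relative: per-column depth factors are absorbed, so
  # normalized columns agree up to a single global factor
  m2 <- sweep(m, 2, c(2, 5), "*")
  sf3 <- medianOfRatios(m2)
  n1 <- sweep(m, 2, sf, "/")
  n3 <- sweep(m2, 2, sf3, "/")
  expect_equal(n3 / n1, matrix((n3 / n1)[1], 3, 2), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_error(medianOfRatios(cbind(c(0, 1), c(1, 0))),
               "normalization impossible")
})

test_that("size factors agree with the independent DESeq2 implementation", {
  set.seed(4)
  m <- matrix(rnbinom(200 * 8, mu = 100, size = 10), 200, 8)
  expect_equal(unname(medianOfRatios(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-10)
})

test_that("gene filter applies the strict coverage boundaries", {
  T <- 19
  mk <- function(tot) matrix(tot / 2, 1, T)
  ref <- rbind(mk(19.9 * 1), mk(20), matrix(0, 1, T), mk(40))
  ref[1, ] <- 19.9 / 2
  alt <- ref
  # gene 3: all zero (both rules); gene 4 has 8 zero timepoints
  ref[4, 1:8] <- 0; alt[4, 1:8] <- 0
  ref[4, 9:T] <- 500; alt[4, 9:T] <- 500
  x <- makeCounts(ref, alt)
  kept <- filterGenes(x)
  expect_false("gene1" %in% kept)  # mean 19.9 < 20 removed
  expect_true("gene2" %in% kept)   # mean exactly 20 retained
  expect_false("gene3" %in% kept)  # all-zero removed
  expect_false("gene4" %in% kept)  # 8 > 7 zero timepoints removed
  # exactly 7 zero timepoints is retained
  ref5 <- matrix(500, 1, T); ref5[1, 1:7] <- 0
  x5 <- makeCounts(ref5, ref5)
  expect_identical(filterGenes(x5), "gene1")
})

test_that("allele frequencies and weights follow the contract", {
  # two genes with opposite imbalance keep the ref/alt size factors equal
  ref <- rbind(matrix(30, 1, 5), matrix(10, 1, 5))
  alt <- rbind(matrix(10, 1, 5), matrix(30, 1, 5))
  x <- makeCounts(ref, alt)
  expect_true(all(abs(diff(normalizeAlleleCounts(x)$sizeFactors)) < 1e-12))
  af <- alleleFrequency(x)
  expect_equal(unname(af$f[1, ]), rep(0.75, 5))
  expect_equal(unname(af$w[1, ]), rep(40, 5))
  # equal counts -> f = 0.5 everywhere
  y <- makeCounts(matrix(7, 2, 5), matrix(7, 2, 5))
  expect_true(all(alleleFrequency(y)$f == 0.5))
  # zero-coverage timepoint is undefined and excluded from the tests
  ref[1, 3] <- 0; alt[1, 3] <- 0
  z <- makeCounts(ref, alt)
  afz <- alleleFrequency(z)
  expect_true(is.na(afz$f[1, 3]))
  lv <- testAseLevels(afz$f[1, ], afz$w[1, ])
  expect_equal(lv$df, 3L)
})

test_that("levels test reproduces the weighted-mean oracle", {
  r <- testAseLevels(c(0.6, 0.7), c(100, 300))
  expect_equal(r$beta0, (100 * 0.1 + 300 * 0.2) / 400)
  expect_equal(r$beta0, 0.175)
  # f identically 0.5: beta0 = 0, p = 1
  r0 <- testAseLevels(rep(0.5, 6), rep(10, 6))
  expect_equal(r0$beta0, 0)
  expect_equal(r0$p, 1)
  # equal weights reduce to the unweighted mean
  f <- c(0.52, 0.48, 0.55, 0.61)
  re <- testAseLevels(f, rep(7, 4))
  expect_equal(re$beta0, mean(f - 0.5))
  # agreement with the independent weighted lm route
  w <- c(10, 40, 25, 5)
  fit <- summary(lm(I(f - 0.5) ~ 1, weights = w))$coefficients
  rw <- testAseLevels(f, w)
  expect_equal(rw$beta0, unname(fit[1, 1]), tolerance = 1e-12)
  expect_equal(rw$se, unname(fit[1, 2]), tolerance = 1e-12)
  expect_equal(rw$p, unname(fit[1, 4]), tolerance = 1e-12)
  expect_true(testAseLevels(c(0.5, NA), c(3, 0))$untestable)
})

test_that("weighted DW statistic evaluates the printed formula", {
  expect_equal(weightedDwStat(c(0.1, 0.1, -0.1, -0.1)), 1.0)
  expect_equal(weightedDwStat(c(0.1, -0.1, 0.1, -0.1)), 3.0)
  expect_equal(weightedDwStat(rep(0, 5)), 2)
  # weights enter as u = w * e
  e <- c(0.1, -0.2, 0.05, 0.1)
  w <- c(2, 1, 3, 1)
  u <- w * e
  expect_equal(weightedDwStat(e, w), sum(diff(u)^2) / sum(u^2))
})

test_that("unit-weight DW equals the classical statistic on 1000 series", {
  skip_if_not_installed("lmtest")
  set.seed(42)
  for (i in 1:1000) {
    f <- runif(sample(5:25, 1))
    e <- f - mean(f)
    expect_equal(weightedDwStat(e), classicalDw(f), tolerance = 1e-12)
  }
})

test_that("dynamics test detects autocorrelated residuals and is exact on nulls", {
  t <- 0:18
  f <- 0.5 + 0.15 * exp(-((t - 8) / 2.5)^2)
  w <- rep(600, 19)
  r <- testAseDynamics(f + rnorm(19, sd = 0.01), w, nPerm = 1000, seed = 1)
  expect_lt(r$dw, 1)
  expect_lt(r$p, 0.01)
  # all-zero residuals: dw = 2, p = 1 convention
  r0 <- testAseDynamics(rep(0.5, 10), rep(5, 10))
  expect_equal(r0$dw, 2)
  expect_equal(r0$p, 1)
  expect_true(testAseDynamics(c(0.4, 0.5, 0.6), c(1, 1, 1))$untestable)
  # reversal leaves dw of a symmetric residual series unchanged
  fs <- 0.5 + c(0.1, 0.05, -0.05, -0.1, -0.1, -0.05, 0.05, 0.1)
  expect_equal(testAseDynamics(fs, rep(1, 8), nPerm = 10, seed = 1)$dw,
               testAseDynamics(rev(fs), rep(1, 8), nPerm = 10,
                               seed = 1)$dw)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bhAdjust(0.04), 0.04)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.9)), c(0.03, 0.03, 0.9))
  expect_equal(bhAdjust(rep(1, 4)), rep(1, 4))
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("both tests give uniform p-values on null simulations", {
  # exchangeable null: flat trajectories, Poisson counts (the read-count
  # weights then match the sampling variance exactly); expression
  # trajectories induce weight heteroskedasticity that makes the dynamics
  # test mildly anti-conservative, mirroring the small number of
  # permutation-validation false positives the pipeline itself reports
  sim <- simulateAseCounts(2000, depth = 600, dispersion = 0,
                           shape = "flat", seed = 21)
  res <- aseTest(sim$counts, nPerm = 1000, seed = 3)
  ksL <- suppressWarnings(ks.test(res$p_levels, "punif"))
  ksD <- suppressWarnings(ks.test(res$p_dyn, "punif"))
  expect_gt(ksL$p.value, 0.01)
  expect_gt(ksD$p.value, 0.01)
})

test_that("dynamics outpowers levels on delay genes; levels is strong on level genes", {
  # high-depth, low-noise seeded scenario with a sizable affected fraction
  sim <- simulateAseCounts(300, depth = 1e4, dispersion = 0.002,
                           effectMix = c(delay = 0.3), seed = 11)
  res <- aseTest(sim$counts, nPerm = 1000, seed = 1)
  tr <- sim$truth[match(res$gene, sim$truth$gene), ]
  sel <- tr$kind == "delay"
  dynRate <- mean(res$q_dyn[sel] < 0.01, na.rm = TRUE)
  levRate <- mean(res$q_levels[sel] < 0.01, na.rm = TRUE)
  expect_gt(dynRate, 0.3)
  expect_gte(dynRate, 5 * levRate)
  simL <- simulateAseCounts(200, depth = 600,
                            effectMix = c(level = 0.3), seed = 12)
  resL <- aseTest(simL$counts, nPerm = 200, seed = 1)
  trL <- simL$truth[match(resL$gene, simL$truth$gene), ]
  expect_gt(mean(resL$q_levels[trL$kind == "level"] < 0.01, na.rm = TRUE),
            0.9)
})

test_that("scaling one allele shifts beta0 but not the null dynamics p-values", {
  # on raw (un-normalized) frequency series; the joint normalization would
  # absorb an allele-wide constant by design
  sim <- simulateAseCounts(500, depth = 600, seed = 31)
  x <- sim$counts[filterGenes(sim$counts), ]
  xs <- AlleleCounts(refCounts(x) * 3, altCounts(x),
                     timepoints = samplingTimes(x))
  rawAf <- function(z) alleleFrequency(z, normalized = list(counts = z))
  af1 <- rawAf(x); af2 <- rawAf(xs)
  b1 <- vapply(seq_len(nrow(x)), function(g)
    testAseLevels(af1$f[g, ], af1$w[g, ])$beta0, numeric(1))
  b2 <- vapply(seq_len(nrow(x)), function(g)
    testAseLevels(af2$f[g, ], af2$w[g, ])$beta0, numeric(1))
  expect_gt(mean(b2), mean(b1) + 0.1)
  p1 <- asedyn:::aseDynamicsBatch(af1$f, af1$w, 300, seed = 2)$p
  p2 <- asedyn:::aseDynamicsBatch(af2$f, af2$w, 300, seed = 3)$p
  ks <- suppressWarnings(ks.test(p1, p2))
  expect_gt(ks$p.value, 0.01)
})

test_that("permutation nulls are seeded, sized and near-zero on null data", {
  sim <- simulateAseCounts(400, depth = 600, seed = 41)
  x <- sim$counts[filterGenes(sim$counts), ]
  expect_identical(permutationNullLevels(x, nPerm = 0), integer(0))
  a <- permutationNullLevels(x, nPerm = 3, seed = 5)
  b <- permutationNullLevels(x, nPerm = 3, seed = 5)
  expect_identical(a, b)
  expect_length(a, 3)
  expect_lte(mean(a), 2)
  d <- permutationNullDynamics(x, nPerm = 2, seed = 5, nInnerPerm = 300)
  expect_length(d, 2)
  expect_lte(mean(d), 5)
  # identity ordering reproduces the unpermuted analysis
  af <- alleleFrequency(x)
  pRef <- asedyn:::aseDynamicsBatch(af$f, af$w, 300,
                                    seed = asedyn:::childSeed(5, "inner"))$p
  nIdent <- permutationNullDynamics(x, nPerm = 1, seed = 5,
                                    nInnerPerm = 300,
                                    orderings = list(seq_len(ncol(x))))
  expect_identical(nIdent[1], sum(bhAdjust(pRef) < 0.01, na.rm = TRUE))
})

test_that("the full pipeline returns a coherent results table", {
  sim <- simulateAseCounts(150, depth = 300,
                           effectMix = c(level = 0.2), seed = 51)
  res <- aseTest(sim$counts, nPerm = 200, seed = 1)
  expect_true(all(c("gene", "beta0", "p_levels", "q_levels", "dw",
                    "p_dyn", "q_dyn") %in% colnames(res)))
  expect_true(all(res$beta0 >= -0.5 & res$beta0 <= 0.5, na.rm = TRUE))
  expect_true(all(res$p_levels >= 0 & res$p_levels <= 1, na.rm = TRUE))
  expect_true(all(res$q_dyn >= res$p_dyn, na.rm = TRUE))
  expect_true(all(res$dw >= 0, na.rm = TRUE))
})
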