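# Shared small library fixture with two parental alleles and chimeras.
twoAlleleManifest <- function(nBarcodes = 4, seed = 3,
                              labels = c("P1", "P2")) {
  bcs <- generateBarcodes(length(labels) * nBarcodes, seed = seed)
  data.frame(construct_id = rep(labels, each = nBarcodes),
             gene = "geneX", region_index = 0,
             allele_label = rep(labels, each = nBarcodes),
             variant_ids = "", barcode = bcs)
}

test_that("barcode counting is exact-match only and round-trips", {
  mf <- twoAlleleManifest(nBarcodes = 2)
  cc <- simulateCreCounts(mf, rbind(P1 = rep(2, 4), P2 = rep(1, 4)),
                          dnaDepth = 50, dispersion = 0, seed = 8)
  # expand counts back into reads and re-count them
  rnaReads <- lapply(seq_len(ncol(rnaCounts(cc))), function(j)
    rep(rownames(rnaCounts(cc)), rnaCounts(cc)[, j]))
  dnaReads <- lapply(seq_len(ncol(dnaCounts(cc))), function(j)
    rep(rownames(dnaCounts(cc)), dnaCounts(cc)[, j]))
  cc2 <- countBarcodes(rnaReads, dnaReads, mf)
  expect_equal(unname(rnaCounts(cc2)), unname(rnaCounts(cc)))
  expect_equal(unname(dnaCounts(cc2)), unname(dnaCounts(cc)))
  # a 1-mismatch read is discarded, not counted
  bc <- mf$barcode[1]
  mut <- bc; substr(mut, 1, 1) <- setdiff(c("A", "C", "G", "T"),
                                          substr(bc, 1, 1))[1]
  cc3 <- countBarcodes(list(c(bc, mut)), list(character(0)), mf)
  expect_equal(sum(rnaCounts(cc3)), 1)
  expect_equal(unname(attr(cc3, "unmatched")["rna"]), 1)
  # empty read set gives all zeros
  cc4 <- countBarcodes(list(character(0)), list(character(0)), mf)
  expect_true(all(rnaCounts(cc4) == 0))
  mfDup <- rbind(mf, mf[1, ])
  expect_error(countBarcodes(list(), list(), mfDup), "duplicate")
})

test_that("CRE filter applies the zero-fraction and mean thresholds", {
  mf <- twoAlleleManifest(nBarcodes = 2)
  T <- 19
  rna <- matrix(500, 4, T, dimnames = list(mf$barcode, NULL))
  dna <- matrix(500, 4, 2, dimnames = list(mf$barcode, NULL))
  rna[1, 1:7] <- 0           # 7 of 19 zero samples: > 19/3, removed
  rna[2, 1:6] <- 0           # 6 of 19: retained
  dna[3, ] <- 99             # mean DNA 99 < 100: removed
  rna[4, ] <- 100            # mean RNA exactly 100: retained
  cc <- CreCounts(rna, dna, mf)
  kept <- filterCres(cc)
  expect_setequal(kept, mf$barcode[c(2, 4)])
})

test_that("expression is the ratio of normalized RNA to the DNA reference", {
  mf <- twoAlleleManifest(nBarcodes = 2)
  # equal RNA and DNA everywhere: expression identically 1
  rna <- matrix(400, 4, 5, dimnames = list(mf$barcode, NULL))
  dna <- matrix(400, 4, 2, dimnames = list(mf$barcode, NULL))
  ce <- creExpression(CreCounts(rna, dna, mf))
  expect_true(all(abs(ce$expression - 1) < 1e-12))
  # doubling one barcode's RNA at one timepoint doubles its expression
  # there only (the column median, hence the size factor, is unmoved)
  rna2 <- rna; rna2[1, 3] <- 800
  ce2 <- creExpression(CreCounts(rna2, dna, mf))
  expect_equal(ce2$expression[1, 3], 2 * ce2$expression[1, 1],
               tolerance = 1e-12)
  expect_equal(ce2$expression[2, ], ce$expression[2, ],
               tolerance = 1e-12)
  # hand-computed 3-barcode fixture with unequal depths
  rna3 <- rbind(b1 = c(100, 200), b2 = c(300, 600), b3 = c(500, 1000))
  dna3 <- cbind(c(50, 150, 250), c(50, 150, 250))
  rownames(dna3) <- rownames(rna3)
  mf3 <- data.frame(construct_id = c("c1", "c1", "c2"),
                    gene = "g", region_index = 0,
                    allele_label = "P1", barcode = c("b1", "b2", "b3"))
  cc3 <- CreCounts(rna3, dna3, mf3)
  sf <- medianOfRatios(cbind(rna3, dna3))
  expRef <- sweep(rna3, 2, sf[1:2], "/") /
    rowMeans(sweep(dna3, 2, sf[3:4], "/"))
  ce3 <- creExpression(cc3)
  expect_equal(unname(ce3$expression), unname(expRef), tolerance = 1e-12)
  # zero RNA counts are missing data, zero DNA drops the barcode
  rna4 <- rna; rna4[2, 4] <- 0
  dna4 <- dna; dna4[3, ] <- 0
  ce4 <- creExpression(CreCounts(rna4, dna4, mf))
  expect_true(is.na(ce4$expression[2, 4]))
  expect_false(mf$barcode[3] %in% rownames(ce4$expression))
  expect_equal(ce4$droppedDnaZero, mf$barcode[3])
})

test_that("round trip from simulation through expression recovers the curves", {
  # a trajectory-diverse library: symmetric up/down pairs keep the
  # per-sample median ratio depth-identifiable, as in a real library
  # where thousands of CREs rise and fall independently
  t <- 0:18
  g <- plogis(1.0 * (t - 8))
  curves <- rbind(exp(outer(seq(0.3, 1.2, length.out = 5), g)),
                  exp(outer(-seq(0.3, 1.2, length.out = 5), g)),
                  matrix(1, 2, 19))
  rownames(curves) <- sprintf("c%02d", seq_len(nrow(curves)))
  mf <- data.frame(construct_id = rep(rownames(curves), each = 4),
                   gene = "g", region_index = 0,
                   allele_label = rep(rownames(curves), each = 4))
  mf$barcode <- generateBarcodes(nrow(mf), seed = 3)
  cc <- simulateCreCounts(mf, curves, dnaDepth = 1e4, dispersion = 0.002,
                          seed = 12)
  ce <- creExpression(cc, filterCres(cc))
  est <- constructSeries(ce)[rownames(curves), ]
  for (i in seq_len(nrow(curves))) {
    relErr <- sqrt(mean((est[i, ] - curves[i, ])^2)) / mean(curves[i, ])
    expect_lt(relErr, 0.1)
  }
})

test_that("timepoint mapping and endogenous correlation behave", {
  s <- c(1, 3, 7, 2, 9, 4)
  expect_equal(correlateWithEndogenous(s, s)$r, 1)
  expect_equal(correlateWithEndogenous(s, -s)$r, -1)
  expect_true(correlateWithEndogenous(rep(1, 6), s)$flagged)
  # 27 reporter timepoints mapped to 19 RNA-seq times: unique and ordered
  creT <- seq(6, 15, length.out = 27)
  rnaT <- seq(6, 15, length.out = 19)
  idx <- mapTimepoints(creT, rnaT)
  expect_length(idx, 19)
  expect_false(is.unsorted(idx))
  expect_equal(anyDuplicated(idx), 0)
  # ties go to the earlier sample
  expect_equal(mapTimepoints(c(0, 2), 1), 1)
})

test_that("level and dynamics tests are calibrated and powered on constructs", {
  mf <- twoAlleleManifest(nBarcodes = 4)
  tp <- trajectoryParams(2, 6, t50 = 8, slope = 1, shape = "increase")
  # same distribution in both alleles: level p uniform over simulations
  pvals <- vapply(1:400, function(r) {
    cc <- simulateCreCounts(mf, list(P1 = tp, P2 = tp), dnaDepth = 1000,
                            dispersion = 0.01, seed = 4000 + r)
    ce <- creExpression(cc)
    testCreLevels(ce, mf$barcode, mf$allele_label)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
  # 2-fold level shift with little noise: detected
  tp2 <- trajectoryParams(4, 12, t50 = 8, slope = 1, shape = "increase")
  cc2 <- simulateCreCounts(mf, list(P1 = tp, P2 = tp2), dnaDepth = 1e4,
                           dispersion = 1e-3, seed = 5)
  ce2 <- creExpression(cc2)
  expect_lt(testCreLevels(ce2, mf$barcode, mf$allele_label)$p, 0.01)
  # a global offset on one barcode must not create a dynamics signal
  ce3 <- creExpression(simulateCreCounts(mf, list(P1 = tp, P2 = tp),
                                         dnaDepth = 1e4,
                                         dispersion = 1e-3, seed = 6))
  ce3$expression[1, ] <- ce3$expression[1, ] * 10
  dyn3 <- testCreDynamics(ce3, mf$barcode, mf$allele_label,
                          nPerm = 500, seed = 1)
  expect_gt(dyn3$p, 0.05)
  # delay-shifted allele: dynamics detected with high power at depth 1e4
  tpDelay <- trajectoryParams(2, 6, t50 = 10.5, slope = 1,
                              shape = "increase")
  ccD <- simulateCreCounts(mf, list(P1 = tp, P2 = tpDelay),
                           dnaDepth = 1e4, dispersion = 1e-3, seed = 7)
  ceD <- creExpression(ccD)
  dynD <- testCreDynamics(ceD, mf$barcode, mf$allele_label,
                          nPerm = 1000, seed = 1)
  expect_lt(dynD$p, 0.05)
})

test_that("variant grouping pools swaps by their focal-variant genotype", {
  labels <- c("P1", "P2", "swap:v1:P2inP1", "swap:v1:P1inP2",
              "swap:v2:P2inP1", "swap:v2:P1inP2", "chimera:P1-P2")
  g1 <- asedyn:::genotypeAtVariant(labels, "v1")
  expect_equal(g1, c("P1", "P2", "P2", "P1", "P1", "P2", NA))
  # k = 1 region: variant test degenerates to the parental-allele test
  mf <- twoAlleleManifest(nBarcodes = 4)
  mf$variant_ids <- "v9"
  tp <- trajectoryParams(2, 6, t50 = 8, slope = 1, shape = "increase")
  tpD <- trajectoryParams(2, 6, t50 = 10.5, slope = 1, shape = "increase")
  cc <- simulateCreCounts(mf, list(P1 = tp, P2 = tpD), dnaDepth = 1e4,
                          dispersion = 1e-3, seed = 9)
  ce <- creExpression(cc)
  vt <- testVariant(ce, mf, nPerm = 500, seed = 1)
  direct <- testCreDynamics(ce, mf$barcode, mf$allele_label,
                            nPerm = 500, seed = 1)
  expect_equal(vt$p_dyn, direct$p)
  expect_equal(vt$n_P1, 4)
  expect_false(vt$untestable)
})

test_that("chimera mapping localizes a proximal-half effect", {
  labels <- c("P1", "P2", "chimera:P1-P2", "chimera:P2-P1")
  nOk <- 0
  for (r in 1:10) {
    mf <- twoAlleleManifest(nBarcodes = 4, seed = 100 + r, labels = labels)
    base <- trajectoryParams(2, 6, t50 = 8, slope = 1, shape = "increase")
    shifted <- trajectoryParams(2, 6, t50 = 10.5, slope = 1,
                                shape = "increase")
    # effect carried by the proximal half: P2 and chimera:P1-P2 share it
    effs <- list("P1" = base, "P2" = shifted,
                 "chimera:P1-P2" = shifted, "chimera:P2-P1" = base)
    cc <- simulateCreCounts(mf, effs, dnaDepth = 1e4, dispersion = 2e-3,
                            seed = 200 + r)
    ce <- creExpression(cc)
    mc <- mapChimera(ce, mf, alpha = 0.05, nPerm = 500, seed = 1)
    if (identical(mc$classification, "proximal")) nOk <- nOk + 1
  }
  expect_gte(nOk, 9)
  # no parental difference: neither
  mf0 <- twoAlleleManifest(nBarcodes = 4, seed = 55, labels = labels)
  base <- trajectoryParams(2, 6, t50 = 8, slope = 1, shape = "increase")
  cc0 <- simulateCreCounts(mf0, setNames(rep(list(base), 4), labels),
                           dnaDepth = 1e4, dispersion = 2e-3, seed = 56)
  mc0 <- mapChimera(creExpression(cc0), mf0, alpha = 0.01,
                    nPerm = 500, seed = 1)
  expect_identical(mc0$classification, "neither")
  # missing chimeras give NA
  mfP <- twoAlleleManifest(nBarcodes = 4, seed = 57)
  ccP <- simulateCreCounts(mfP, list(P1 = base, P2 = base),
                           dnaDepth = 1e4, seed = 58)
  expect_true(is.na(mapChimera(creExpression(ccP), mfP)$classification))
})

test_that("chimera range classification reproduces the geometry oracles", {
  # chimera equal to one parent is inside with no outside timepoints
  p1 <- c(1, 2, 3); p2 <- c(2, 3, 4)
  r1 <- classifyChimeraRange(p1, p2, p1)
  expect_identical(r1$range, "inside")
  expect_equal(r1$d_cp_mean, r1$d_pp / 2)
  expect_equal(r1$n_outside_timepoints, 0)
  # hand-computed 2-point geometry: parents (0,0) and (2,0), chimera (1,3)
  r2 <- classifyChimeraRange(c(0, 0), c(2, 0), c(1, 3))
  expect_equal(r2$d_pp, 2)
  expect_equal(r2$d_cp_mean, sqrt(10))
  expect_identical(r2$range, "outside")
  expect_equal(r2$n_outside_timepoints, 1)
  # midpoint chimera is inside everywhere
  r3 <- classifyChimeraRange(c(0, 4), c(2, 0), c(1, 2))
  expect_identical(r3$range, "inside")
  expect_equal(r3$n_outside_timepoints, 0)
  # any convex combination is inside (property over random cases)
  set.seed(10)
  for (i in 1:50) {
    a <- runif(8); b <- runif(8); lam <- runif(8)
    ch <- lam * a + (1 - lam) * b
    expect_identical(classifyChimeraRange(a, b, ch)$range, "inside")
    expect_equal(classifyChimeraRange(a, b, ch)$n_outside_timepoints, 0)
  }
})

test_that("variant summaries report the SNP to InDel ratio", {
  res <- data.frame(type = rep(c("SNP", "DEL"), c(57, 13)),
                    significant = rep(c(TRUE, FALSE, TRUE, FALSE),
                                      c(30, 27, 5, 8)))
  s <- summarizeVariantTests(res)
  expect_equal(s$n_snp_sig, 30)
  expect_equal(s$n_indel_sig, 5)
  expect_equal(s$snp_indel_ratio, 6)
})
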