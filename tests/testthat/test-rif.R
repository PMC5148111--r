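# Build a dataset whose group means and within-group correlations are
# exactly controlled, to pin the RIF formulas down by arithmetic.
rifFixture <- function(eTH, eDH, rTH, rDH, n = 6, seed = 71) {
  # one regulator ("tr"), DE probes de1..deK with target group means and
  # (via shared latents) target correlations
  set.seed(seed)
  K <- length(eTH)
  z1 <- scale(rnorm(n)); z2 <- scale(rnorm(n))   # regulator latents
  m <- matrix(0, K + 1, 2 * n)
  rownames(m) <- c("tr", paste0("de", seq_len(K)))
  colnames(m) <- c(paste0("TH_", 1:n), paste0("DH_", 1:n))
  m["tr", ] <- c(10 + as.vector(z1), 10 + as.vector(z2))
  for (i in seq_len(K)) {
    n1 <- scale(resid(lm(rnorm(n) ~ z1)))  # orthogonal noise
    n2 <- scale(resid(lm(rnorm(n) ~ z2)))
    t1 <- rTH[i] * z1 + sqrt(1 - rTH[i]^2) * n1
    t2 <- rDH[i] * z2 + sqrt(1 - rDH[i]^2) * n2
    # scale() standardizes with sd 1 so empirical corr is exactly rTH/rDH
    m[i + 1, ] <- c(eTH[i] + as.vector(t1) - mean(t1),
                    eDH[i] + as.vector(t2) - mean(t2))
  }
  list(m = m, groups = rep(c("TH", "DH"), each = n))
}

test_that("RIF1 matches the PIF-weighted squared differential-wiring formula", {
  # single DE gene: a = 10, de = 2, r1 = 1 (use 0.999... via direct), r2 = 0
  fx <- rifFixture(eTH = 11, eDH = 9, rTH = 1, rDH = 0)
  rif <- computeRif(fx$m, fx$groups, trProbes = "tr", deProbes = "de1")
  # a = 10, de = 2, dw = 1 - 0 = 1 -> RIF1 = 10 * 2 * 1 = 20
  expect_equal(rif$rif1, 20, tolerance = 1e-8)
  # no rewiring -> RIF1 = 0
  fx0 <- rifFixture(eTH = 11, eDH = 9, rTH = 0.6, rDH = 0.6)
  rif0 <- computeRif(fx0$m, fx0$groups, trProbes = "tr", deProbes = "de1")
  expect_equal(rif0$rif1, 0, tolerance = 1e-8)
  # averaging: contributions 20 and -4 -> RIF1 = 8
  # second gene: a = 10, de = -2, dw^2 = 0.2^2... use dw = 1: a*de = -20?
  # choose: gene2 a = 2, de = -2, dw = 1 -> contribution -4
  fx2 <- rifFixture(eTH = c(11, 1), eDH = c(9, 3), rTH = c(1, 1),
                    rDH = c(0, 0))
  rif2 <- computeRif(fx2$m, fx2$groups, trProbes = "tr",
                     deProbes = c("de1", "de2"))
  expect_equal(rif2$rif1, (20 + (-4)) / 2, tolerance = 1e-8)
})

test_that("RIF2 matches the difference of squared expression-correlation products", {
  # e1 = 2, r1 = 1, e2 = 2, r2 = 0 -> RIF2 = (2*1)^2 - (2*0)^2 = 4
  fx <- rifFixture(eTH = 2, eDH = 2, rTH = 1, rDH = 0)
  rif <- computeRif(fx$m, fx$groups, trProbes = "tr", deProbes = "de1")
  expect_equal(rif$rif2, 4, tolerance = 1e-8)
  # symmetric groups -> RIF2 = 0
  fxS <- rifFixture(eTH = 5, eDH = 5, rTH = 0.7, rDH = 0.7)
  rifS <- computeRif(fxS$m, fxS$groups, trProbes = "tr", deProbes = "de1")
  expect_equal(rifS$rif2, 0, tolerance = 1e-8)
  # swapping the groups negates RIF2
  fxA <- rifFixture(eTH = 3, eDH = 6, rTH = 0.9, rDH = 0.2)
  a <- computeRif(fxA$m, fxA$groups, trProbes = "tr", deProbes = "de1")
  b <- computeRif(fxA$m, fxA$groups, trProbes = "tr", deProbes = "de1",
                  group1 = "DH", group2 = "TH")
  expect_equal(b$rif2, -a$rif2, tolerance = 1e-8)
})

test_that("z-standardization uses the sample s.d. and flags degeneracy", {
  zr <- zscoreRank(c(1, 2, 3), ids = c("a", "b", "c"), k = 1)
  expect_equal(zr$table$z, c(-1, 0, 1))  # sample sd of (1,2,3) is 1
  expect_identical(zr$topPositive, "c")
  expect_identical(zr$topNegative, "a")
  expect_error(zscoreRank(c(2, 2, 2)), "zero standard deviation")
  expect_error(zscoreRank(c(1, NA, NA)), "at least 2")
  # z-scores invariant to affine transformation of the raw scores
  raw <- c(4, 7, 1, 9, 3)
  z1 <- zscoreRank(raw)$table$z
  z2 <- zscoreRank(3 * raw - 11)$table$z
  expect_equal(z1, z2, tolerance = 1e-12)
  # extreme counts
  set.seed(1)
  zr2 <- zscoreRank(c(rnorm(20), 50, -60))
  expect_gte(zr2$nPositiveExtreme, 1)
  expect_gte(zr2$nNegativeExtreme, 1)
})

test_that("z1/z2 have mean 0 and sample s.d. 1 over scored regulators", {
  sim <- simulateDataset(simConfig(nGenes = 200, nPerGroup = 8,
                                   nRegulators = 6,
                                   targetsPerRegulator = 5, seed = 81))
  m <- intensities(sim$dataset)
  gmap <- unname(probeGenes(sim$dataset))
  trP <- rownames(m)[gmap %in% regulatorIds(sim$truth)]
  deP <- rownames(m)[gmap %in% deBreedGenes(sim$truth)]
  rif <- computeRif(m, groupLabels(sim$dataset), trP, deP)
  expect_equal(mean(rif$z1), 0, tolerance = 1e-10)
  expect_equal(sd(rif$z1), 1, tolerance = 1e-10)
  expect_equal(mean(rif$z2), 0, tolerance = 1e-10)
  expect_equal(sd(rif$z2), 1, tolerance = 1e-10)
})

test_that("a regulator with no valid DE pairing is unscored, not zero", {
  fx <- rifFixture(eTH = c(11, 9), eDH = c(9, 11), rTH = c(0.8, 0.1),
                   rDH = c(0.1, 0.8), n = 8)
  m <- rbind(fx$m, flat = rep(5, ncol(fx$m)))  # zero variance regulator
  rif <- computeRif(m, fx$groups, trProbes = c("tr", "flat"),
                    deProbes = c("de1", "de2"))
  expect_true(is.na(rif$rif1[rif$tr == "flat"]))
  expect_equal(rif$nDe[rif$tr == "flat"], 0)
  expect_false(is.na(rif$rif1[rif$tr == "tr"]))
})

test_that("a planted rewired regulator dominates the RIF1 ranking", {
  hits <- 0L
  nRep <- 10L
  for (s in seq_len(nRep)) {
    sim <- simulateDataset(simConfig(nGenes = 300, nPerGroup = 20,
                                     fracDeBreed = 0.1,
                                     fracDeInteraction = 0,
                                     nRegulators = 1,
                                     targetsPerRegulator = 15,
                                     wiringRGroup1 = 0.9,
                                     wiringRGroup2 = 0, noiseSd = 0.5,
                                     probeNoiseSd = 0, fracAbsent = 0,
                                     seed = 900 + s))
    m <- intensities(sim$dataset)
    gmap <- unname(probeGenes(sim$dataset))
    planted <- regulatorIds(sim$truth)
    set.seed(1000 + s)
    nullTr <- sample(setdiff(
      gmap[!gmap %in% c(deBreedGenes(sim$truth), planted)],
      unlist(regulatorTargets(sim$truth))), 50)
    trP <- rownames(m)[match(c(planted, nullTr), gmap)]
    deP <- rownames(m)[gmap %in% deBreedGenes(sim$truth)]
    rif <- computeRif(m, groupLabels(sim$dataset), trP, deP)
    rk <- regulatorRanks(rif, rownames(m)[match(planted, gmap)], "z1")
    if (!is.na(rk) && rk == 1L) hits <- hits + 1L
  }
  expect_gte(hits / nRep, 0.9)
})
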