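test_that("invalid configurations are rejected naming the field", {
  expect_error(simConfig(fracDeBreed = 1.2), "fracDeBreed")
  expect_error(simConfig(fracAbsent = -0.1), "fracAbsent")
  expect_error(simConfig(wiringRGroup1 = 1.5), "wiringRGroup1")
  expect_error(simConfig(nPerGroup = 0), "nPerGroup")
  expect_error(simConfig(noiseSd = -1), "noiseSd")
})

test_that("no planted effects gives empty truth sets", {
  sim <- simulateDataset(simConfig(nGenes = 50, fracDeBreed = 0,
                                   fracDeInteraction = 0, nRegulators = 0,
                                   fracAbsent = 0, nPerGroup = 2, seed = 5))
  expect_length(deBreedGenes(sim$truth), 0)
  expect_length(deInteractionGenes(sim$truth), 0)
  expect_length(regulatorIds(sim$truth), 0)
})

test_that("identical seeds reproduce the dataset exactly", {
  cfg <- simConfig(nGenes = 120, nPerGroup = 3, probesPerGene = 2, seed = 1)
  a <- simulateDataset(cfg)
  b <- simulateDataset(cfg)
  expect_identical(intensities(a$dataset), intensities(b$dataset))
  expect_identical(detectionFlags(a$dataset), detectionFlags(b$dataset))
  expect_identical(deBreedGenes(a$truth), deBreedGenes(b$truth))
  c <- simulateDataset(simConfig(nGenes = 120, nPerGroup = 3,
                                 probesPerGene = 2, seed = 2))
  expect_false(identical(intensities(a$dataset), intensities(c$dataset)))
})

test_that("planted breed effect is recovered from the emitted matrix", {
  cfg <- simConfig(nGenes = 2000, nPerGroup = 10, effectSizeBreed = 2.0,
                   noiseSd = 0.5, probeNoiseSd = 0, fracAbsent = 0,
                   nRegulators = 0, seed = 7)
  sim <- simulateDataset(cfg)
  m <- intensities(sim$dataset)
  d <- sampleDesign(sim$dataset)
  deProbes <- rownames(m)[unname(probeGenes(sim$dataset)) %in%
                            deBreedGenes(sim$truth)]
  diffs <- rowMeans(m[deProbes, d$breed == "Tibetan"]) -
    rowMeans(m[deProbes, d$breed == "Duroc"])
  # per-gene diff has sd noiseSd*sqrt(2/20); the average over genes has
  # that over sqrt(nGenes)
  se <- 0.5 * sqrt(2 / 20) / sqrt(length(deProbes))
  expect_lt(abs(mean(diffs) - 2.0), 3 * se)
})

test_that("interaction effect is confined to the high-altitude cells", {
  sim <- simulateDataset(simConfig(nGenes = 500, nPerGroup = 10,
                                   fracDeBreed = 0,
                                   effectSizeInteraction = 3,
                                   noiseSd = 0.3, probeNoiseSd = 0,
                                   fracAbsent = 0, nRegulators = 0,
                                   seed = 11))
  m <- intensities(sim$dataset)
  g <- groupLabels(sim$dataset)
  p <- rownames(m)[unname(probeGenes(sim$dataset)) %in%
                     deInteractionGenes(sim$truth)]
  dHigh <- mean(rowMeans(m[p, g == "TH"]) - rowMeans(m[p, g == "DH"]))
  dLow <- mean(rowMeans(m[p, g == "TL"]) - rowMeans(m[p, g == "DL"]))
  expect_lt(abs(dHigh - 3), 0.1)
  expect_lt(abs(dLow), 0.1)
})

test_that("planted wiring reproduces the target correlations on average", {
  cfg <- simConfig(nGenes = 400, nPerGroup = 20, nRegulators = 4,
                   targetsPerRegulator = 15, wiringRGroup1 = 0.9,
                   wiringRGroup2 = 0, probeNoiseSd = 0, fracAbsent = 0,
                   seed = 13)
  sim <- simulateDataset(cfg)
  m <- intensities(sim$dataset)
  g <- groupLabels(sim$dataset)
  gmap <- unname(probeGenes(sim$dataset))
  probeOf <- function(gene) rownames(m)[match(gene, gmap)]
  r1 <- c(); r2 <- c()
  for (rg in regulatorIds(sim$truth)) {
    pr <- probeOf(rg)
    for (tg in regulatorTargets(sim$truth)[[rg]]) {
      pt <- probeOf(tg)
      r1 <- c(r1, cor(m[pr, g == "TH"], m[pt, g == "TH"]))
      r2 <- c(r2, cor(m[pr, g == "DH"], m[pt, g == "DH"]))
    }
  }
  expect_lt(abs(mean(r1) - 0.9), 0.1)
  expect_lt(abs(mean(r2) - 0.0), 0.1)
})

test_that("absent probes sit at background and flag A everywhere", {
  cfg <- simConfig(nGenes = 1000, nPerGroup = 4, fracAbsent = 0.2,
                   fracDeBreed = 0.05, fracDeInteraction = 0.05,
                   nRegulators = 0, seed = 17)
  sim <- simulateDataset(cfg)
  fl <- detectionFlags(sim$dataset)
  allA <- rownames(fl)[rowSums(fl == "P") == 0]
  # every planted absent probe is all-A; a handful of genes with naturally
  # low baselines may join them
  expect_true(all(absentProbes(sim$truth) %in% allA))
  fracAllA <- length(allA) / nrow(fl)
  expect_lt(abs(fracAllA - 0.2), 0.02)
  # truth sets never overlap absent probes' genes
  absGenes <- unname(probeGenes(sim$dataset)[absentProbes(sim$truth)])
  expect_length(intersect(absGenes, deBreedGenes(sim$truth)), 0)
  expect_length(intersect(absGenes, deInteractionGenes(sim$truth)), 0)
})

test_that("truthEval counts recovery as defined", {
  tr <- c("a", "b", "c")
  expect_equal(truthEval(tr, tr)$sensitivity, 1.0)
  expect_equal(truthEval(tr, tr)$fdp, 0.0)
  e <- truthEval(character(), tr)
  expect_equal(e$sensitivity, 0.0)
  expect_equal(e$fdp, 0.0)
  # 8 true calls of 9 plus one extra -> FDP 1/9
  called <- c(paste0("t", 1:8), "extra")
  truth <- paste0("t", 1:8)
  expect_equal(truthEval(called, truth)$fdp, 1 / 9)
  expect_true(is.na(truthEval(called, character())$sensitivity))
})
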