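test_that("constant response gives zero sums of squares and p = 1", {
  b <- rep(c("T", "D"), each = 6)
  a <- rep(c("H", "L"), 6)
  res <- twoWayAnova(rep(4.2, 12), b, a)
  expect_equal(res$p, rep(1, 3))
  expect_equal(res$F, rep(0, 3))
})

test_that("zero residual variance with a real effect reports p = 0", {
  b <- rep(c("T", "D"), each = 4)
  a <- rep(c("H", "L"), 4)
  y <- ifelse(b == "T", 10, 8)  # exact breed effect, no noise
  res <- twoWayAnova(y, b, a)
  expect_equal(res$p[res$effect == "breed"], 0)
  expect_equal(res$p[res$effect == "interaction"], 1)
})

test_that("F and p match the least-squares model-comparison oracle", {
  set.seed(21)
  for (i in 1:25) {
    # balanced and unbalanced cell sizes
    ns <- if (i %% 2 == 0) rep(3, 4) else sample(2:5, 4, replace = TRUE)
    b <- rep(rep(c("T", "D"), each = 2), times = ns)
    a <- rep(rep(c("H", "L"), 2), times = ns)
    y <- rnorm(length(b)) + rnorm(1) * (b == "T") + rnorm(1) * (a == "H")
    mine <- twoWayAnova(y, b, a)
    orac <- lmAnovaOracle(y, b, a)
    expect_lt(max(abs(mine$F - orac$F)), 1e-10)
    expect_lt(max(abs(mine$p - orac$p)), 1e-10)
  }
})

test_that("Type-II sums of squares agree with car::Anova on unbalanced data", {
  skip_if_not_installed("car")
  set.seed(31)
  ns <- c(2, 4, 3, 5)
  b <- factor(rep(rep(c("T", "D"), each = 2), times = ns))
  a <- factor(rep(rep(c("H", "L"), 2), times = ns))
  y <- rnorm(length(b), mean = 2 * (b == "T"))
  fit <- stats::lm(y ~ b * a)
  ca <- car::Anova(fit, type = 2)
  mine <- twoWayAnova(y, b, a)
  expect_equal(mine$F, ca$`F value`[1:3], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(mine$p, ca$`Pr(>F)`[1:3], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("missing factor level or empty cell is an error", {
  b <- rep("T", 8)
  a <- rep(c("H", "L"), 4)
  expect_error(twoWayAnova(rnorm(8), b, a), "two levels")
  b2 <- c(rep("T", 4), rep("D", 4))
  a2 <- c(rep("H", 4), rep("L", 4))  # T*L and D*H cells empty
  expect_error(twoWayAnova(rnorm(8), b2, a2), "cell")
})

test_that("runAnova vectorizes twoWayAnova over probes", {
  d <- tinyDataset(nPerGroup = 3, nProbes = 6)
  tab <- runAnova(d)
  des <- sampleDesign(d)
  for (i in c(1, 4)) {
    single <- twoWayAnova(intensities(d)[i, ], des$breed, des$altitude)
    expect_equal(tab$F_breed[i], single$F[1], tolerance = 1e-12)
    expect_equal(tab$p_interaction[i], single$p[3], tolerance = 1e-12)
  }
  expect_equal(tab$q_breed, bhFdr(tab$p_breed))
})

test_that("BH step-up q-values follow the hand-applied rule", {
  expect_equal(bhFdr(0.03), 0.03)                  # m = 1
  expect_equal(bhFdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bhFdr(rep(0.2, 5)), rep(0.2, 5))    # all equal
  # hand computation for a mixed vector
  p <- c(0.001, 0.04, 0.03, 0.8)
  # sorted: .001 .03 .04 .8 -> m*p/j: .004 .06 .05333 .8
  # step-up minima: .004 .05333 .05333 .8
  expect_equal(bhFdr(p), c(0.004, 4 * 0.04 / 3, 4 * 0.04 / 3, 0.8),
               tolerance = 1e-12)
  expect_error(bhFdr(c(0.1, 1.2)), "\\[0,1\\]")
  # permutation invariance
  set.seed(2)
  pp <- runif(50)
  perm <- sample(50)
  expect_equal(bhFdr(pp)[perm], bhFdr(pp[perm]))
})

test_that("q-values dominate p-values and are monotone in p", {
  set.seed(3)
  p <- runif(200)
  q <- bhFdr(p)
  expect_true(all(q >= p - 1e-15))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
})

test_that("type-I error is calibrated under a global null", {
  sim <- simulateDataset(simConfig(nGenes = 5000, nPerGroup = 4,
                                   fracDeBreed = 0, fracDeInteraction = 0,
                                   nRegulators = 0, fracAbsent = 0,
                                   probesPerGene = 1, probeNoiseSd = 0,
                                   seed = 41))
  tab <- runAnova(sim$dataset)
  ci <- qnorm(0.995) * sqrt(0.05 * 0.95 / 5000)
  for (p in list(tab$p_breed, tab$p_altitude, tab$p_interaction)) {
    expect_lt(abs(mean(p < 0.05) - 0.05), ci + 1e-12)
    expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
  }
})

test_that("selectDegs requires both breed and interaction significance", {
  tab <- data.frame(probe = c("a", "b", "c"),
                    q_breed = c(1e-5, 1e-5, 0.5),
                    q_interaction = c(0.5, 1e-5, 1e-5))
  expect_identical(selectDegs(tab, alpha = 1e-4)$probes, "b")
  # gene collapse keeps the most significant probe per gene
  tab2 <- data.frame(probe = c("p1", "p2", "p3"),
                     q_breed = c(1e-6, 1e-9, 1e-6),
                     q_interaction = c(1e-6, 1e-9, 1e-6))
  ann <- data.frame(probe = c("p1", "p2", "p3"),
                    gene = c("G1", "G1", "G2"))
  sel <- selectDegs(tab2, alpha = 1e-4, annotation = ann)
  expect_identical(sel$genes, c("G1", "G2"))
  expect_identical(unname(sel$geneProbes["G1"]), "p2")
})

test_that("planted interaction+breed genes are recovered; breed-only are not called", {
  sim <- simulateDataset(simConfig(nGenes = 800, nPerGroup = 8,
                                   fracDeBreed = 0.1,
                                   fracDeInteraction = 0.1,
                                   effectSizeBreed = 2, noiseSd = 0.5,
                                   effectSizeInteraction = 2,
                                   probesPerGene = 1, probeNoiseSd = 0,
                                   nRegulators = 0, fracAbsent = 0,
                                   seed = 51))
  tab <- runAnova(sim$dataset)
  ann <- sim$annotation
  sel <- selectDegs(tab, alpha = 1e-3, annotation = ann)
  # the call is strongly enriched for interaction+breed genes over
  # breed-only genes, and clean of false discoveries
  nInter <- length(intersect(sel$genes, deInteractionGenes(sim$truth)))
  nBreedOnly <- length(intersect(sel$genes, deBreedGenes(sim$truth)))
  expect_gt(nInter, 10 * max(1, nBreedOnly))
  ev <- truthEval(sel$genes, sim$truth, "interaction")
  expect_gt(ev$sensitivity, 0.5)
  expect_lte(ev$fdp, 0.1)
  # median p_breed over planted breed genes far below the DEG threshold
  bp <- tab$p_breed[ann$gene[match(tab$probe, ann$probe)] %in%
                      deBreedGenes(sim$truth)]
  expect_lt(median(bp), 1e-4)
})
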