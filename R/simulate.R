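#' Simulation configuration for the 2x2 migrant design
#'
#' Builds and validates the parameter set for [simulateDataset()]. The
#' defaults describe a desk-scale version of the migrant study design: four
#' groups (TH, TL, DH, DL), log2-scale Gaussian noise, ~10% of genes
#' differentially expressed, a handful of planted regulators whose wiring to
#' their targets differs between the Tibetan and Duroc high-altitude groups,
#' and a fraction of probes left at background ("absent") signal.
#'
#' @param nGenes number of genes.
#' @param probesPerGene probes per gene (>= 1); replicate probes share the
#'   gene's transcript signal plus independent technical noise.
#' @param nPerGroup animals per design cell. The real study used 2; with
#'   n = 2 within-group correlations are degenerate (only +/-1), so the
#'   default is 8 (see the package vignette).
#' @param fracDeBreed,fracDeInteraction fractions in [0,1] of genes planted
#'   with a breed main effect / a breed-by-altitude interaction effect.
#'   The two gene sets are sampled disjointly.
#' @param effectSizeBreed,effectSizeInteraction log2-scale mean shifts.
#' @param nRegulators number of planted regulator genes.
#' @param targetsPerRegulator targets per regulator, drawn from the breed-DE
#'   gene pool when available.
#' @param wiringRGroup1 target regulator-target correlation within the TH
#'   group (in [-1,1]).
#' @param wiringRGroup2 target correlation within DH (also used for the
#'   low-altitude cells).
#' @param noiseSd log2-scale residual standard deviation of the transcript
#'   signal.
#' @param probeNoiseSd log2-scale technical noise added independently per
#'   probe on top of the transcript signal; set to 0 for exact planted
#'   correlations.
#' @param fracAbsent fraction of probes placed at background.
#' @param baselineMean,baselineSd per-gene log2 baseline distribution.
#' @param backgroundMean,backgroundSd raw-scale background signal
#'   distribution used both to draw absent-probe intensities and to call
#'   detection flags (see [callDetection()]).
#' @param detectionK detection threshold multiplier: a cell is present when
#'   its raw signal exceeds backgroundMean + detectionK * backgroundSd.
#' @param seed integer RNG seed.
#' @return a validated list of class \code{"SimConfig"}.
#' @export
simConfig <- function(nGenes = 2000L, probesPerGene = 1L, nPerGroup = 8L,
                      fracDeBreed = 0.1, fracDeInteraction = 0.1,
                      effectSizeBreed = 2.0, effectSizeInteraction = 2.0,
                      nRegulators = 5L, targetsPerRegulator = 10L,
                      wiringRGroup1 = 0.9, wiringRGroup2 = 0,
                      noiseSd = 0.5, probeNoiseSd = 0.1,
                      fracAbsent = 0.05,
                      baselineMean = 10, baselineSd = 1.2,
                      backgroundMean = 100, backgroundSd = 20,
                      detectionK = 2, seed = 1L) {
  cfg <- list(nGenes = as.integer(nGenes),
              probesPerGene = as.integer(probesPerGene),
              nPerGroup = as.integer(nPerGroup),
              fracDeBreed = fracDeBreed,
              fracDeInteraction = fracDeInteraction,
              effectSizeBreed = effectSizeBreed,
              effectSizeInteraction = effectSizeInteraction,
              nRegulators = as.integer(nRegulators),
              targetsPerRegulator = as.integer(targetsPerRegulator),
              wiringRGroup1 = wiringRGroup1,
              wiringRGroup2 = wiringRGroup2,
              noiseSd = noiseSd, probeNoiseSd = probeNoiseSd,
              fracAbsent = fracAbsent,
              baselineMean = baselineMean, baselineSd = baselineSd,
              backgroundMean = backgroundMean, backgroundSd = backgroundSd,
              detectionK = detectionK, seed = as.integer(seed))
  for (f in c("fracDeBreed", "fracDeInteraction", "fracAbsent")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("invalid SimConfig: '%s' must be a fraction in [0,1]", f))
  }
  for (f in c("wiringRGroup1", "wiringRGroup2")) {
    if (abs(cfg[[f]]) > 1)
      stop(sprintf("invalid SimConfig: '%s' must lie in [-1,1]", f))
  }
  for (f in c("nGenes", "probesPerGene", "nPerGroup")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop(sprintf("invalid SimConfig: '%s' must be a positive integer", f))
  }
  for (f in c("noiseSd", "probeNoiseSd", "baselineSd", "backgroundSd")) {
    if (cfg[[f]] < 0)
      stop(sprintf("invalid SimConfig: '%s' must be non-negative", f))
  }
  if (cfg$nRegulators < 0L || cfg$targetsPerRegulator < 0L)
    stop("invalid SimConfig: 'nRegulators'/'targetsPerRegulator' must be >= 0")
  if (cfg$backgroundMean <= 0)
    stop("invalid SimConfig: 'backgroundMean' must be positive")
  class(cfg) <- "SimConfig"
  cfg
}

# background draw truncated below the detection threshold, so an "absent"
# cell can never flag present
rtruncBackground <- function(n, mean, sd, k) {
  hi <- mean + k * sd
  lo <- 0
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Simulate a migrant-design expression dataset with known truth
#'
#' Generates a probe-level log2 intensity matrix over the four groups TH,
#' TL, DH and DL with: per-gene Gaussian baselines; a breed main-effect
#' shift for the planted breed-DE genes (both altitudes); an additional
#' shift confined to the Tibetan high-altitude cell for the planted
#' interaction genes; regulator genes whose targets are generated from the
#' regulator's standardized latent signal as
#' \code{target = r * z_reg + sqrt(1 - r^2) * z_noise}, giving an expected
#' regulator-target correlation of exactly \code{r} within each group
#' (wiringRGroup1 in TH, wiringRGroup2 elsewhere); and a fraction of
#' probes drawn from background signal and flagged absent. Detection flags
#' are produced by [callDetection()] on the raw-scale matrix, so flags and
#' intensities are self-consistent. Identical seeds give identical output.
#'
#' @param config a [simConfig()] object.
#' @return list with elements:
#'   \describe{
#'     \item{dataset}{a [MigrantArrayExperiment-class].}
#'     \item{truth}{a [SimTruth-class].}
#'     \item{regulators}{character vector of planted regulator genes.}
#'     \item{annotation}{data.frame(probe, gene).}
#'   }
#' @examples
#' sim <- simulateDataset(simConfig(nGenes = 100, nPerGroup = 3, seed = 42))
#' sim$dataset
#' sim$truth
#' @export
simulateDataset <- function(config) {
  if (!inherits(config, "SimConfig")) config <- do.call(simConfig, config)
  cfg <- config
  set.seed(cfg$seed)

  genes <- sprintf("G%05d", seq_len(cfg$nGenes))
  free <- genes
  nDeB <- round(cfg$fracDeBreed * cfg$nGenes)
  deBreed <- sort(sample(free, nDeB))
  free <- setdiff(free, deBreed)
  nDeI <- min(round(cfg$fracDeInteraction * cfg$nGenes), length(free))
  deInter <- sort(sample(free, nDeI))
  free <- setdiff(free, deInter)
  nReg <- min(cfg$nRegulators, length(free))
  regulators <- sort(sample(free, nReg))
  free <- setdiff(free, regulators)

  # targets come from the DE pools first (regulators drive DE genes) —
  # interaction genes, the pipeline's DEG call, before breed-only genes —
  # topped up from unplanted genes; disjoint across regulators
  targets <- list()
  poolDe <- c(deInter, deBreed)
  for (rg in regulators) {
    take <- character()
    nWant <- cfg$targetsPerRegulator
    if (length(poolDe) && nWant > 0) {
      take <- sample(poolDe, min(nWant, length(poolDe)))
      poolDe <- setdiff(poolDe, take)
    }
    if (length(take) < nWant && length(free)) {
      extra <- sample(free, min(nWant - length(take), length(free)))
      free <- setdiff(free, extra)
      take <- c(take, extra)
    }
    targets[[rg]] <- sort(take)
  }

  # samples
  grid <- expand.grid(altitude = c("high", "low"),
                      breed = c("Tibetan", "Duroc"),
                      stringsAsFactors = FALSE)[, 2:1]
  grid <- grid[order(match(grid$breed, c("Tibetan", "Duroc")),
                     match(grid$altitude, c("high", "low"))), ]
  design <- data.frame(
    breed = rep(grid$breed, each = cfg$nPerGroup),
    altitude = rep(grid$altitude, each = cfg$nPerGroup),
    stringsAsFactors = FALSE)
  design$group <- paste0(toupper(substring(design$breed, 1, 1)),
                         toupper(substring(design$altitude, 1, 1)))
  design$sample <- paste0(design$group,
                          "_", ave(seq_len(nrow(design)), design$group,
                                   FUN = seq_along))
  nS <- nrow(design)

  # per-gene cell means
  baseline <- stats::rnorm(cfg$nGenes, cfg$baselineMean, cfg$baselineSd)
  names(baseline) <- genes
  mu <- matrix(rep(baseline, nS), cfg$nGenes, nS,
               dimnames = list(genes, design$sample))
  isTib <- design$breed == "Tibetan"
  isHigh <- design$altitude == "high"
  mu[deBreed, isTib] <- mu[deBreed, isTib] + cfg$effectSizeBreed
  mu[deInter, isTib & isHigh] <- mu[deInter, isTib & isHigh] +
    cfg$effectSizeInteraction

  # transcript-level residuals (standardized), with wiring for reg/targets
  resid <- matrix(stats::rnorm(cfg$nGenes * nS), cfg$nGenes, nS,
                  dimnames = list(genes, design$sample))
  if (length(regulators)) {
    wir <- ifelse(design$group == "TH", cfg$wiringRGroup1, cfg$wiringRGroup2)
    for (rg in regulators) {
      zreg <- resid[rg, ]
      for (tg in targets[[rg]]) {
        eps <- stats::rnorm(nS)
        resid[tg, ] <- wir * zreg + sqrt(1 - wir^2) * eps
      }
    }
  }
  exprGene <- mu + cfg$noiseSd * resid

  # probe level
  probes <- as.vector(t(outer(genes, seq_len(cfg$probesPerGene),
                              function(g, k) sprintf("%s_%02d", g, k))))
  probeGene <- rep(genes, each = cfg$probesPerGene)
  expr <- exprGene[probeGene, , drop = FALSE]
  rownames(expr) <- probes
  if (cfg$probeNoiseSd > 0)
    expr <- expr + matrix(stats::rnorm(length(expr), 0, cfg$probeNoiseSd),
                          nrow(expr), ncol(expr))

  # absent probes: only probes of unplanted genes; values at background
  nAbs <- round(cfg$fracAbsent * length(probes))
  freeProbes <- probes[probeGene %in% free]
  if (nAbs > length(freeProbes)) {
    warning("fracAbsent exceeds the unplanted probe pool; truncating")
    nAbs <- length(freeProbes)
  }
  absent <- sort(sample(freeProbes, nAbs))
  raw <- 2^expr
  if (length(absent)) {
    bg <- rtruncBackground(length(absent) * nS, cfg$backgroundMean,
                           cfg$backgroundSd, cfg$detectionK)
    raw[absent, ] <- matrix(bg, length(absent), nS)
    expr[absent, ] <- log2(raw[absent, , drop = FALSE])
  }
  flags <- callDetection(raw, cfg$backgroundMean, cfg$backgroundSd,
                         cfg$detectionK)

  annotation <- data.frame(probe = probes, gene = probeGene,
                           stringsAsFactors = FALSE)
  dataset <- MigrantArrayExperiment(
    expr, design[, c("sample", "breed", "altitude")],
    flags = flags, probeAnnotation = annotation)
  truth <- new("SimTruth",
               deBreedGenes = deBreed, deInteractionGenes = deInter,
               regulatorIds = regulators, regulatorTargets = targets,
               absentProbes = absent)
  list(dataset = dataset, truth = truth, regulators = regulators,
       annotation = annotation)
}

#' Score called gene sets against simulation truth
#'
#' @param called character vector of called gene (or probe) ids.
#' @param truth character vector of true ids, or a [SimTruth-class] plus
#'   \code{what} naming the truth slot to use.
#' @param what when \code{truth} is a SimTruth: one of
#'   \code{"interaction"}, \code{"breed"} (which truth gene set to score
#'   against).
#' @return list with \code{sensitivity} (\code{NA} when the truth set is
#'   empty), \code{fdp} (false discovery proportion,
#'   |called \\ truth| / max(1, |called|)), \code{nCalled}, \code{nTruth}.
#' @examples
#' truthEval(c("a", "b"), c("a", "b"))          # sens 1, fdp 0
#' truthEval(character(), c("a", "b"))          # sens 0, fdp 0
#' @export
truthEval <- function(called, truth, what = c("interaction", "breed")) {
  if (is(truth, "SimTruth")) {
    what <- match.arg(what)
    truth <- if (what == "interaction") deInteractionGenes(truth)
             else deBreedGenes(truth)
  }
  called <- unique(as.character(called))
  truth <- unique(as.character(truth))
  tp <- length(intersect(called, truth))
  sens <- if (length(truth) == 0L) NA_real_ else tp / length(truth)
  fdp <- (length(called) - tp) / max(1L, length(called))
  list(sensitivity = sens, fdp = fdp,
       nCalled = length(called), nTruth = length(truth))
}

#' Rank planted regulators in a RIF table
#'
#' Position of each given regulator in the ordering of scored regulators by
#' decreasing absolute z-score (ties broken by id).
#'
#' @param rif a RIF table from [computeRif()].
#' @param ids regulator ids (values of \code{rif$tr}) to look up.
#' @param score which z-score column to rank on: "z1" or "z2".
#' @return named integer vector of ranks (1 = largest |z|); NA for
#'   regulators that are unscored or missing.
#' @export
regulatorRanks <- function(rif, ids, score = c("z1", "z2")) {
  score <- match.arg(score)
  z <- rif[[score]]
  ok <- !is.na(z)
  ord <- order(-abs(z[ok]), rif$tr[ok])
  rk <- rep(NA_integer_, nrow(rif))
  rk[ok][ord] <- seq_len(sum(ok))
  names(rk) <- rif$tr
  out <- rk[ids]
  names(out) <- ids
  out
}

#' Simulate a term-to-gene annotation
#'
#' Draws random, possibly overlapping gene sets over a gene universe, for
#' exercising [enrich()] on synthetic data.
#'
#' @param genes gene universe.
#' @param nTerms number of terms.
#' @param meanSize mean term size (sizes are Poisson around this, min 2).
#' @param seed RNG seed.
#' @return named list term -> gene character vector, with a
#'   \code{"descriptions"} attribute.
#' @export
simulateAnnotation <- function(genes, nTerms = 20L, meanSize = 50L,
                               seed = 1L) {
  set.seed(seed)
  sizes <- pmax(2L, stats::rpois(nTerms, meanSize))
  sizes <- pmin(sizes, length(genes))
  ann <- lapply(sizes, function(s) sort(sample(genes, s)))
  names(ann) <- sprintf("TERM%04d", seq_len(nTerms))
  attr(ann, "descriptions") <- sprintf("synthetic term %d", seq_len(nTerms))
  ann
}
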