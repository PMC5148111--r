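# Independent oracles used across the suite. These deliberately take the
# slow, obvious route (lm model comparison, exhaustive triple loops,
# enumeration) so they share no code with the implementation they check.

# full-vs-reduced least-squares oracle for the two-way ANOVA (Type II)
lmAnovaOracle <- function(y, breed, altitude) {
  breed <- factor(breed); altitude <- factor(altitude)
  rss <- function(fm) sum(stats::residuals(stats::lm(fm))^2)
  rFull <- rss(y ~ breed * altitude)
  rSR <- rss(y ~ breed + altitude)
  rS <- rss(y ~ breed)
  rR <- rss(y ~ altitude)
  dfRes <- length(y) - 4L
  msRes <- rFull / dfRes
  Fb <- (rR - rSR) / msRes
  Fa <- (rS - rSR) / msRes
  Fi <- (rSR - rFull) / msRes
  data.frame(effect = c("breed", "altitude", "interaction"),
             F = c(Fb, Fa, Fi),
             p = stats::pf(c(Fb, Fa, Fi), 1, dfRes, lower.tail = FALSE))
}

# exhaustive O(n^3) PCIT oracle: literal trio loop, same tolerance rule
pcitOracle <- function(corr, tol = 1e-12) {
  n <- nrow(corr)
  r <- corr
  off <- abs(r) >= 1; diag(off) <- FALSE
  r[off] <- sign(r[off]) * (1 - 1e-12)
  mask <- matrix(TRUE, n, n, dimnames = dimnames(corr))
  pc <- function(a, b, c) (r[a, b] - r[a, c] * r[b, c]) /
    sqrt((1 - r[a, c]^2) * (1 - r[b, c]^2))
  for (x in 1:(n - 2)) for (y in (x + 1):(n - 1)) for (z in (y + 1):n) {
    rxy.z <- pc(x, y, z); rxz.y <- pc(x, z, y); ryz.x <- pc(y, z, x)
    terms <- c(if (abs(r[x, y]) >= tol) rxy.z / r[x, y],
               if (abs(r[x, z]) >= tol) rxz.y / r[x, z],
               if (abs(r[y, z]) >= tol) ryz.x / r[y, z])
    if (!length(terms)) next
    eps <- mean(terms)
    if (abs(r[x, y]) < abs(eps * r[x, z]) &&
        abs(r[x, y]) < abs(eps * r[y, z]))
      mask[x, y] <- mask[y, x] <- FALSE
    if (abs(r[x, z]) < abs(eps * r[x, y]) &&
        abs(r[x, z]) < abs(eps * r[y, z]))
      mask[x, z] <- mask[z, x] <- FALSE
    if (abs(r[y, z]) < abs(eps * r[x, y]) &&
        abs(r[y, z]) < abs(eps * r[x, z]))
      mask[y, z] <- mask[z, y] <- FALSE
  }
  mask
}

# random correlation-like matrix: correlation of random Gaussian data
randomCorr <- function(nGenes, nSamples = 10, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(nGenes * nSamples), nGenes, nSamples)
  rownames(x) <- sprintf("g%02d", seq_len(nGenes))
  suppressWarnings(stats::cor(t(x)))
}

# exhaustive hypergeometric tail by enumeration over draw compositions
hyperTailOracle <- function(count, ref, total, listSize, upper = TRUE) {
  ks <- 0:min(ref, listSize)
  probs <- choose(ref, ks) * choose(total - ref, listSize - ks) /
    choose(total, listSize)
  if (upper) sum(probs[ks >= count]) else sum(probs[ks <= count])
}

# small handmade 2x2 dataset
tinyDataset <- function(nPerGroup = 2, nProbes = 3, seed = 99) {
  set.seed(seed)
  groups <- rep(c("TH", "TL", "DH", "DL"), each = nPerGroup)
  design <- data.frame(
    sample = paste0(groups, "_", rep(seq_len(nPerGroup), 4)),
    breed = rep(c("Tibetan", "Duroc"), each = 2 * nPerGroup),
    altitude = rep(rep(c("high", "low"), each = nPerGroup), 2))
  m <- matrix(round(rnorm(nProbes * length(groups), 10, 1), 3),
              nProbes, length(groups),
              dimnames = list(sprintf("p%02d", seq_len(nProbes)),
                              design$sample))
  MigrantArrayExperiment(m, design)
}
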