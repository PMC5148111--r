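#' Regulatory impact factor (RIF1/RIF2) scoring
#'
#' Scores each candidate transcriptional regulator against a set of
#' differentially expressed (DE) probes, contrasting two sample groups
#' (by default TH vs DH, the two breeds at high altitude). With, for DE
#' probe i: \code{e1_i}/\code{e2_i} the group-mean log2 expression,
#' \code{a_i = (e1_i + e2_i)/2}, \code{de_i = e1_i - e2_i}, and
#' \code{r1_ij}/\code{r2_ij} the within-group Pearson correlation between
#' regulator j and probe i, the raw scores are
#' \deqn{RIF1_j = \frac{1}{n_{DE}} \sum_i a_i\, de_i\, (r1_{ij} - r2_{ij})^2}
#' \deqn{RIF2_j = \frac{1}{n_{DE}} \sum_i (e1_i r1_{ij})^2 - (e2_i r2_{ij})^2}
#' RIF1 flags regulators whose wiring to abundant, strongly DE genes
#' changes most between the groups; RIF2 flags regulators whose expression
#' best predicts DE-gene abundance. z-scores standardize each raw score
#' over the scored regulators (sample standard deviation, n-1).
#'
#' Regulator-probe pairs with an undefined correlation (zero variance
#' within a group) are dropped from that regulator's average; a regulator
#' with no valid pairing is reported unscored (NA), not zero, and excluded
#' from the z-standardization.
#'
#' @param x probe x sample log2 matrix or a [MigrantArrayExperiment-class].
#' @param groups per-sample group labels (ignored for a
#'   MigrantArrayExperiment).
#' @param trProbes probe ids of the candidate regulators (must be rows of
#'   \code{x}; ids absent from the matrix are dropped with a warning).
#' @param deProbes probe ids of the DE set.
#' @param group1,group2 contrasted groups (defaults "TH", "DH").
#' @return data.frame(tr, nDe, rif1, rif2, z1, z2), one row per regulator
#'   in input order; \code{nDe} counts the valid DE pairings.
#' @seealso [zscoreRank()] for rankings and top-k selections.
#' @export
computeRif <- function(x, groups = NULL, trProbes, deProbes,
                       group1 = "TH", group2 = "DH") {
  if (is(x, "MigrantArrayExperiment")) {
    groups <- groupLabels(x)
    x <- intensities(x)
  }
  x <- as.matrix(x)
  missTr <- setdiff(trProbes, rownames(x))
  if (length(missTr)) {
    warning(length(missTr), " regulator probes absent from the matrix; dropped")
    trProbes <- intersect(trProbes, rownames(x))
  }
  deProbes <- intersect(deProbes, rownames(x))
  if (!length(trProbes)) stop("no regulator probe present in the matrix")
  if (!length(deProbes)) stop("no DE probe present in the matrix")
  for (g in c(group1, group2))
    if (!g %in% groups) stop(sprintf("unknown group label '%s'", g))
  m1 <- x[, groups == group1, drop = FALSE]
  m2 <- x[, groups == group2, drop = FALSE]
  if (ncol(m1) < 2L || ncol(m2) < 2L)
    stop("both groups need >= 2 samples for within-group correlations")

  e1 <- rowMeans(m1[deProbes, , drop = FALSE])
  e2 <- rowMeans(m2[deProbes, , drop = FALSE])
  a <- (e1 + e2) / 2
  de <- e1 - e2
  r1 <- suppressWarnings(stats::cor(t(m1[trProbes, , drop = FALSE]),
                                    t(m1[deProbes, , drop = FALSE])))
  r2 <- suppressWarnings(stats::cor(t(m2[trProbes, , drop = FALSE]),
                                    t(m2[deProbes, , drop = FALSE])))
  dw <- r1 - r2
  c1 <- sweep(dw^2, 2, a * de, "*")
  c2 <- sweep(r1^2, 2, e1^2, "*") - sweep(r2^2, 2, e2^2, "*")
  valid <- !is.na(c1)
  nDe <- rowSums(valid)
  rif1 <- rowMeans(c1, na.rm = TRUE)
  rif2 <- rowMeans(c2, na.rm = TRUE)
  rif1[nDe == 0L] <- NA_real_
  rif2[nDe == 0L] <- NA_real_

  zstd <- function(raw) {
    ok <- !is.na(raw)
    if (sum(ok) >= 2L && stats::sd(raw[ok]) > 0)
      (raw - mean(raw[ok])) / stats::sd(raw[ok])
    else rep(NA_real_, length(raw))
  }
  data.frame(tr = trProbes, nDe = nDe, rif1 = rif1, rif2 = rif2,
             z1 = zstd(rif1), z2 = zstd(rif2),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' z-standardize raw scores and pick top regulators
#'
#' Standardizes raw scores over the scored (non-NA) entries using the
#' sample standard deviation, ranks them, and reports the top-k positive
#' and top-k negative entries (ties broken by decreasing |z| then
#' lexicographic id) together with the counts beyond \code{|z| > zCut}.
#'
#' @param raw numeric raw scores; NAs mark unscored entries.
#' @param ids identifiers, same length as \code{raw}.
#' @param k how many top entries per sign (default 5).
#' @param zCut magnitude threshold for the extreme counts (default 2).
#' @return list: \code{table} (id, raw, z, rank by decreasing z; unscored
#'   rows keep NA), \code{topPositive}, \code{topNegative} (id vectors),
#'   \code{nPositiveExtreme}, \code{nNegativeExtreme}.
#' @export
zscoreRank <- function(raw, ids = names(raw), k = 5L, zCut = 2) {
  if (is.null(ids)) ids <- as.character(seq_along(raw))
  ok <- !is.na(raw)
  if (sum(ok) < 2L)
    stop("need at least 2 scored entries to standardize")
  s <- stats::sd(raw[ok])
  if (s == 0)
    stop("zero standard deviation: raw scores are degenerate (all equal)")
  z <- rep(NA_real_, length(raw))
  z[ok] <- (raw[ok] - mean(raw[ok])) / s
  rank <- rep(NA_integer_, length(raw))
  ordDesc <- order(-z[ok], ids[ok])
  rank[ok][ordDesc] <- seq_len(sum(ok))
  tab <- data.frame(id = ids, raw = raw, z = z, rank = rank,
                    stringsAsFactors = FALSE)
  kk <- min(k, sum(ok))
  topPos <- ids[ok][ordDesc][seq_len(kk)]
  ordAsc <- order(z[ok], ids[ok])
  topNeg <- ids[ok][ordAsc][seq_len(kk)]
  list(table = tab, topPositive = topPos, topNegative = topNeg,
       nPositiveExtreme = sum(z > zCut, na.rm = TRUE),
       nNegativeExtreme = sum(z < -zCut, na.rm = TRUE))
}
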