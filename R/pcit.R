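#' First-order partial correlation
#'
#' Correlation of x and y with z partialled out:
#' \code{(r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))}.
#' Vectorized over its arguments.
#'
#' @param rxy,rxz,ryz pairwise Pearson correlations; \code{|r_xz|} and
#'   \code{|r_yz|} must be < 1.
#' @return the partial correlation r_xy.z.
#' @examples
#' partialCorrelation(0.9, 0.8, 0.8)  # 0.26/0.36
#' @export
partialCorrelation <- function(rxy, rxz, ryz) {
  if (any(abs(rxz) >= 1) || any(abs(ryz) >= 1))
    stop("partial correlation undefined for |conditioning r| = 1")
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

#' Within-group Pearson correlation matrix
#'
#' @param x probe x sample log2 matrix or a [MigrantArrayExperiment-class].
#' @param groups per-sample group labels (ignored for a
#'   MigrantArrayExperiment).
#' @param group group whose samples to correlate over.
#' @return symmetric probe x probe correlation matrix.
#' @export
groupCorrelation <- function(x, groups = NULL, group = "TH") {
  if (is(x, "MigrantArrayExperiment")) {
    groups <- groupLabels(x)
    x <- intensities(x)
  }
  x <- as.matrix(x)
  if (!group %in% groups) stop(sprintf("unknown group label '%s'", group))
  sub <- x[, groups == group, drop = FALSE]
  if (ncol(sub) < 2L)
    stop("correlation requires at least 2 samples in the group")
  suppressWarnings(stats::cor(t(sub)))
}

# clamp correlations of exactly +/-1 off the boundary so partial-correlation
# denominators stay finite; guaranteed to trigger at n = 2 samples per group
.clampCorr <- function(r, eps = 1e-12) {
  off <- abs(r) >= 1
  diag(off) <- FALSE
  if (any(off, na.rm = TRUE)) {
    warning("correlations with |r| = 1 clamped to +/-(1 - 1e-12); ",
            "the group is too small for stable correlation estimates")
    r[off] <- sign(r[off]) * (1 - eps)
  }
  r
}

#' PCIT significance filtering of a correlation matrix
#'
#' Partial correlation and information theory (PCIT) edge filtering: for
#' every trio of genes (x, y, z) the three first-order partial correlations
#' are combined into a local tolerance
#' \code{eps = mean(r_xy.z / r_xy, r_xz.y / r_xz, r_yz.x / r_yz)}, and the
#' edge (x, y) is flagged non-significant if some third gene z satisfies
#' \code{|r_xy| < |eps * r_xz|} and \code{|r_xy| < |eps * r_yz|} — i.e. the
#' association is explained by z. Ratio terms whose denominator |r| is
#' below \code{tol} are dropped from the tolerance average; a trio with no
#' valid term is skipped. Correlations of exactly +/-1 are clamped to
#' +/-(1 - 1e-12) first (with a warning).
#'
#' @param corr symmetric correlation matrix (>= 3 genes for filtering;
#'   with fewer, all edges survive with a warning).
#' @param tol denominators below this magnitude are excluded (default
#'   1e-12).
#' @return symmetric logical matrix; TRUE marks a significant edge
#'   (diagonal TRUE by convention).
#' @examples
#' r <- matrix(c(1, .9, .9, .9, 1, .95, .9, .95, 1), 3, 3)
#' pcitFilter(r)  # all three edges survive
#' @export
pcitFilter <- function(corr, tol = 1e-12) {
  corr <- as.matrix(corr)
  n <- nrow(corr)
  if (n != ncol(corr)) stop("correlation matrix must be square")
  mask <- matrix(TRUE, n, n, dimnames = dimnames(corr))
  if (n < 3L) {
    warning("fewer than 3 genes: PCIT not applicable, all edges survive")
    return(mask)
  }
  rc <- .clampCorr(corr)
  idx <- seq_len(n)
  for (x in 1:(n - 1L)) {
    for (y in (x + 1L):n) {
      z <- idx[-c(x, y)]
      rxy <- rc[x, y]
      rxz <- rc[x, z]
      ryz <- rc[y, z]
      den <- sqrt((1 - rxz^2) * (1 - ryz^2))
      rxy.z <- (rxy - rxz * ryz) / den
      rxz.y <- (rxz - rxy * ryz) / sqrt((1 - rxy^2) * (1 - ryz^2))
      ryz.x <- (ryz - rxy * rxz) / sqrt((1 - rxy^2) * (1 - rxz^2))
      t1 <- if (abs(rxy) < tol) rep(NA_real_, length(z)) else rxy.z / rxy
      t2 <- rxz.y / rxz
      t2[abs(rxz) < tol] <- NA_real_
      t3 <- ryz.x / ryz
      t3[abs(ryz) < tol] <- NA_real_
      nv <- (!is.na(t1)) + (!is.na(t2)) + (!is.na(t3))
      s <- ifelse(is.na(t1), 0, t1) + ifelse(is.na(t2), 0, t2) +
        ifelse(is.na(t3), 0, t3)
      eps <- ifelse(nv > 0L, s / nv, NA_real_)
      dominated <- abs(rxy) < abs(eps * rxz) & abs(rxy) < abs(eps * ryz)
      if (any(dominated, na.rm = TRUE))
        mask[x, y] <- mask[y, x] <- FALSE
    }
  }
  mask
}

#' Threshold significant edges on absolute correlation
#'
#' Keeps the unordered pairs that are PCIT-significant and whose raw
#' correlation magnitude reaches \code{rMin} (default 0.95).
#'
#' @param corr symmetric correlation matrix with dimnames.
#' @param mask logical significance mask from [pcitFilter()].
#' @param rMin absolute-correlation threshold in (0, 1].
#' @param group group tag recorded on each edge (e.g. "TH").
#' @return data.frame(gene_a, gene_b, r, group), rows sorted by
#'   (gene_a, gene_b) with gene_a < gene_b.
#' @export
thresholdEdges <- function(corr, mask, rMin = 0.95, group = NA_character_) {
  if (!is.numeric(rMin) || length(rMin) != 1L || rMin <= 0 || rMin > 1)
    stop("rMin must lie in (0, 1]")
  corr <- as.matrix(corr)
  ids <- rownames(corr)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(corr)))
  sel <- mask & abs(corr) >= rMin
  sel[lower.tri(sel, diag = TRUE)] <- FALSE
  w <- which(sel, arr.ind = TRUE)
  a <- ids[w[, 1]]
  b <- ids[w[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(gene_a = a, gene_b = b, r = corr[w],
                    group = rep(group, length(a)),
                    stringsAsFactors = FALSE)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}
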