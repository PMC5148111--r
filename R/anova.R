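# residual sums of squares of Y (samples x probes) under design matrix X,
# via a single QR projection shared by all probes
.rssProject <- function(Y, X) {
  q <- qr.Q(qr(X))
  res <- Y - q %*% crossprod(q, Y)
  colSums(res^2)
}

.anovaCore <- function(mat, breed, altitude) {
  breed <- droplevels(factor(breed))
  altitude <- droplevels(factor(altitude))
  if (nlevels(breed) != 2L || nlevels(altitude) != 2L)
    stop("both factors must have exactly two levels present")
  if (any(table(breed, altitude) == 0L))
    stop("every breed x altitude cell must contain at least one sample")
  n <- ncol(mat)
  dfRes <- n - 4L
  if (dfRes < 1L) stop("residual degrees of freedom must be >= 1")
  Y <- t(mat)
  rssFull <- .rssProject(Y, stats::model.matrix(~ breed * altitude))
  rssSR   <- .rssProject(Y, stats::model.matrix(~ breed + altitude))
  rssS    <- .rssProject(Y, stats::model.matrix(~ breed))
  rssR    <- .rssProject(Y, stats::model.matrix(~ altitude))
  # Type-II sums of squares (equal to the sequential/balanced decomposition
  # when the design is balanced); each effect has 1 df with 2-level factors
  ssB <- pmax(rssR - rssSR, 0)
  ssA <- pmax(rssS - rssSR, 0)
  ssI <- pmax(rssSR - rssFull, 0)
  msRes <- rssFull / dfRes
  tot <- colSums(Y^2)
  tol <- 1e-12 * pmax(tot, 1)
  fp <- function(ss) {
    Fv <- ss / msRes
    p <- stats::pf(Fv, 1, dfRes, lower.tail = FALSE)
    deg <- msRes <= tol  # zero residual variance
    if (any(deg)) {
      p[deg] <- ifelse(ss[deg] > tol[deg], 0, 1)
      Fv[deg] <- ifelse(ss[deg] > tol[deg], Inf, 0)
    }
    list(F = Fv, p = p)
  }
  list(breed = fp(ssB), altitude = fp(ssA), interaction = fp(ssI),
       dfRes = dfRes)
}

#' Two-way factorial ANOVA for a single response
#'
#' Fits \code{y = mu + breed + altitude + breed:altitude + error} and tests
#' each effect with an F-test against the residual mean square, using
#' Type-II sums of squares (identical to the sequential decomposition for
#' balanced designs). Degenerate responses with zero residual variance
#' report p = 0 for effects with positive sum of squares and p = 1
#' otherwise.
#'
#' @param y numeric response vector, one value per sample.
#' @param breed,altitude per-sample factors, each with both levels present
#'   in every combination.
#' @return data.frame with one row per effect (breed, altitude,
#'   interaction): columns \code{effect}, \code{F}, \code{p}, \code{df1},
#'   \code{df2}.
#' @examples
#' b <- rep(c("T", "D"), each = 6); a <- rep(c("H", "L"), 6)
#' twoWayAnova(rnorm(12), b, a)
#' @export
twoWayAnova <- function(y, breed, altitude) {
  res <- .anovaCore(matrix(as.numeric(y), nrow = 1), breed, altitude)
  data.frame(effect = c("breed", "altitude", "interaction"),
             F = c(res$breed$F, res$altitude$F, res$interaction$F),
             p = c(res$breed$p, res$altitude$p, res$interaction$p),
             df1 = 1L, df2 = res$dfRes,
             stringsAsFactors = FALSE)
}

#' Per-probe two-way ANOVA table with FDR control
#'
#' Applies [twoWayAnova()] to every probe of an expression matrix and
#' appends, per effect, Benjamini-Hochberg q-values computed across
#' probes.
#'
#' @param x probe x sample numeric matrix, or a
#'   [MigrantArrayExperiment-class] (in which case breed/altitude are taken
#'   from its design).
#' @param breed,altitude per-sample factors; ignored when \code{x} is a
#'   MigrantArrayExperiment.
#' @return data.frame with columns \code{probe}, and per effect \code{F_*},
#'   \code{p_*}, \code{q_*} for breed, altitude and interaction.
#' @export
runAnova <- function(x, breed = NULL, altitude = NULL) {
  if (is(x, "MigrantArrayExperiment")) {
    d <- sampleDesign(x)
    breed <- d$breed
    altitude <- d$altitude
    x <- intensities(x)
  }
  x <- as.matrix(x)
  res <- .anovaCore(x, breed, altitude)
  data.frame(probe = rownames(x),
             F_breed = res$breed$F, p_breed = res$breed$p,
             q_breed = bhFdr(res$breed$p),
             F_altitude = res$altitude$F, p_altitude = res$altitude$p,
             q_altitude = bhFdr(res$altitude$p),
             F_interaction = res$interaction$F,
             p_interaction = res$interaction$p,
             q_interaction = bhFdr(res$interaction$p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up q-values
#'
#' \code{q_(i) = min over j >= i of m * p_(j) / j}, returned in the input
#' order.
#'
#' @param p numeric vector of p-values in [0,1].
#' @return q-values of the same length and order.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bhFdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0,1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

#' Select differentially expressed probes and genes
#'
#' A probe is called differentially expressed when it is significant for
#' both the breed main effect and the breed-by-altitude interaction at the
#' given FDR level — the signature of a breed difference that responds to
#' altitude. When an annotation is supplied the call is collapsed to the
#' gene level, keeping each gene's most significant probe (smallest
#' \code{max(q_breed, q_interaction)}).
#'
#' @param anovaTable output of [runAnova()].
#' @param alpha FDR threshold (default 1e-4).
#' @param annotation optional data.frame(probe, gene).
#' @return list with \code{probes} (called probe ids), and when annotation
#'   is given \code{genes} (distinct annotated symbols) and
#'   \code{geneProbes} (named vector gene -> representative probe).
#' @export
selectDegs <- function(anovaTable, alpha = 1e-4, annotation = NULL) {
  stopifnot(all(c("probe", "q_breed", "q_interaction") %in%
                colnames(anovaTable)))
  hit <- anovaTable$q_breed < alpha & anovaTable$q_interaction < alpha
  probes <- anovaTable$probe[hit]
  out <- list(probes = probes)
  if (!is.null(annotation)) {
    ann <- as.data.frame(annotation)
    g <- ann$gene[match(probes, ann$probe)]
    sig <- pmax(anovaTable$q_breed, anovaTable$q_interaction)[hit]
    keep <- !is.na(g)
    df <- data.frame(probe = probes[keep], gene = g[keep], sig = sig[keep],
                     stringsAsFactors = FALSE)
    df <- df[order(df$sig, df$probe), ]
    df <- df[!duplicated(df$gene), ]
    out$genes <- sort(unique(df$gene))
    gp <- df$probe
    names(gp) <- df$gene
    out$geneProbes <- gp[order(names(gp))]
  }
  out
}
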