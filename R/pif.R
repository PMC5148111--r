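#' Phenotype impact factor (PIF) between two sample groups
#'
#' For each probe, with \code{e1}/\code{e2} the mean log2 expression in the
#' two groups: abundance \code{a = (e1 + e2) / 2}, differential expression
#' \code{de = e1 - e2}, and \code{PIF = a * de} — differential expression
#' weighted by overall abundance. Swapping the groups negates \code{de} and
#' \code{PIF} and leaves \code{a} unchanged.
#'
#' @param x probe x sample log2 matrix or a [MigrantArrayExperiment-class].
#' @param groups per-sample group labels (ignored when \code{x} is a
#'   MigrantArrayExperiment, whose group codes are used).
#' @param group1,group2 labels of the two contrasted groups (defaults "TH"
#'   and "DH", the two high-altitude cells).
#' @return data.frame(probe, e1, e2, a, de, pif).
#' @examples
#' m <- rbind(p1 = c(12, 12, 8, 8))
#' computePif(m, groups = c("TH", "TH", "DH", "DH"))  # a 10, de 4, pif 40
#' @export
computePif <- function(x, groups = NULL, group1 = "TH", group2 = "DH") {
  if (is(x, "MigrantArrayExperiment")) {
    groups <- groupLabels(x)
    x <- intensities(x)
  }
  x <- as.matrix(x)
  for (g in c(group1, group2))
    if (!g %in% groups)
      stop(sprintf("unknown group label '%s'", g))
  e1 <- rowMeans(x[, groups == group1, drop = FALSE])
  e2 <- rowMeans(x[, groups == group2, drop = FALSE])
  a <- (e1 + e2) / 2
  de <- e1 - e2
  data.frame(probe = rownames(x), e1 = e1, e2 = e2, a = a, de = de,
             pif = a * de, row.names = NULL, stringsAsFactors = FALSE)
}

#' Differential-PIF test over the full 2x2 design
#'
#' Submits abundance-weighted per-sample values to the same two-way ANOVA
#' and BH-FDR machinery used for differential expression: each sample value
#' is weighted by the probe's grand mean, \code{w_ik = ybar_i * y_ik}, and
#' the selection rule mirrors [selectDegs()] (breed and interaction both
#' significant) at the same FDR level.
#'
#' Note that because the weighting multiplies every sample of a probe by
#' the same constant, and the ANOVA F statistic is invariant to rescaling
#' the response, the differential-PIF p-values coincide with the DEG
#' p-values for every probe with a nonzero grand mean; the call sets are
#' then identical (see the package vignette for discussion). The weighted
#' values themselves — whose group-mean difference estimates the PIF —
#' are what [computePif()] summarizes.
#'
#' @param x probe x sample log2 matrix or a [MigrantArrayExperiment-class].
#' @param breed,altitude per-sample factors (ignored for a
#'   MigrantArrayExperiment).
#' @param alpha FDR threshold (default 1e-4).
#' @return list with \code{probes} (selected differential-PIF probes) and
#'   \code{table}: the weighted-ANOVA table from [runAnova()] plus a
#'   \code{q_pif} column (\code{max(q_breed, q_interaction)}, the binding
#'   constraint of the selection rule).
#' @export
differentialPif <- function(x, breed = NULL, altitude = NULL, alpha = 1e-4) {
  if (is(x, "MigrantArrayExperiment")) {
    d <- sampleDesign(x)
    breed <- d$breed
    altitude <- d$altitude
    x <- intensities(x)
  }
  x <- as.matrix(x)
  w <- x * rowMeans(x)
  tab <- runAnova(w, breed, altitude)
  tab$q_pif <- pmax(tab$q_breed, tab$q_interaction)
  sel <- selectDegs(tab, alpha = alpha)
  list(probes = sel$probes, table = tab)
}
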