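#' Expected annotated-gene count under no enrichment
#'
#' \code{Expected = refCount * listSize / refTotal}: the number of list
#' genes a term would receive if the list were a random draw from the
#' reference.
#'
#' @param refCount genes annotated to the term in the reference.
#' @param listSize size of the gene list.
#' @param refTotal size of the reference universe (> 0).
#' @return the expected count (vectorized over refCount).
#' @examples
#' expectedCount(169, 1062, 20000)
#' @export
expectedCount <- function(refCount, listSize, refTotal) {
  if (refTotal <= 0) stop("refTotal must be positive")
  if (listSize < 0 || listSize > refTotal)
    stop("listSize must lie in [0, refTotal]")
  if (any(refCount < 0 | refCount > refTotal))
    stop("refCount must lie in [0, refTotal]")
  refCount * listSize / refTotal
}

#' Over-representation analysis with fold enrichment
#'
#' For each term: \code{REF} is the number of universe genes annotated to
#' it, \code{Count} the number of list genes annotated, \code{Expected}
#' from [expectedCount()], and \code{fold = Count / Expected}. The raw
#' p-value is the one-sided hypergeometric tail — over-representation
#' (\code{P(X >= Count)}) when \code{Count >= Expected}, the opposite tail
#' otherwise. Both Bonferroni (\code{min(1, m * p)}) and Benjamini-Hochberg
#' adjustments are reported, with m the number of tested terms.
#'
#' @param geneList character vector of genes; must be a non-empty subset of
#'   \code{universe}.
#' @param annotation named list term -> gene character vector; an optional
#'   \code{"descriptions"} attribute supplies term names. Annotated genes
#'   outside the universe are ignored; terms with REF = 0 are skipped.
#' @param universe reference gene universe.
#' @param overOnly report only over-represented rows (direction "+",
#'   the default); adjustment still uses all tested terms.
#' @return data.frame(term, name, ref, count, expected, fold, direction,
#'   p_raw, p_bonferroni, q_bh) sorted by p_raw.
#' @export
enrich <- function(geneList, annotation, universe, overOnly = TRUE) {
  geneList <- unique(as.character(geneList))
  universe <- unique(as.character(universe))
  if (!length(geneList)) stop("gene list is empty")
  bad <- setdiff(geneList, universe)
  if (length(bad))
    stop("gene list contains genes outside the universe: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10))
  descr <- attr(annotation, "descriptions")
  if (is.null(descr)) descr <- names(annotation)
  N <- length(universe)
  L <- length(geneList)
  rows <- lapply(seq_along(annotation), function(i) {
    term <- intersect(annotation[[i]], universe)
    ref <- length(term)
    if (ref == 0L) return(NULL)
    count <- length(intersect(geneList, term))
    exp <- expectedCount(ref, L, N)
    over <- count >= exp
    p <- if (over)
      stats::phyper(count - 1L, ref, N - ref, L, lower.tail = FALSE)
    else
      stats::phyper(count, ref, N - ref, L, lower.tail = TRUE)
    data.frame(term = names(annotation)[i], name = descr[i], ref = ref,
               count = count, expected = exp, fold = count / exp,
               direction = if (count / exp > 1) "+" else "-",
               p_raw = p, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    return(data.frame(term = character(), name = character(),
                      ref = integer(), count = integer(),
                      expected = numeric(), fold = numeric(),
                      direction = character(), p_raw = numeric(),
                      p_bonferroni = numeric(), q_bh = numeric(),
                      stringsAsFactors = FALSE))
  m <- nrow(rows)
  rows$p_bonferroni <- pmin(1, rows$p_raw * m)
  rows$q_bh <- stats::p.adjust(rows$p_raw, method = "BH")
  if (overOnly) rows <- rows[rows$direction == "+", , drop = FALSE]
  rows <- rows[order(rows$p_raw, rows$term), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}
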