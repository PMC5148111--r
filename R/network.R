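#' Extract the top-regulator co-expression subnetwork
#'
#' Seeds the network with the top-k positive and top-k negative regulators
#' by RIF1 and/or RIF2 z-score, adds every edge-set partner of a seed that
#' is a DE or differential-PIF probe, and retains the edges among the
#' resulting node set (all such edges by default, or only edges touching a
#' seed regulator with \code{trIncidentOnly = TRUE}). Seed regulators with
#' no retained partner remain in the network as isolated nodes.
#'
#' @param edges edge data.frame from [thresholdEdges()] (gene_a, gene_b, r,
#'   group), computed within one sample group.
#' @param rif RIF table from [computeRif()].
#' @param degProbes probe ids called differentially expressed.
#' @param pifProbes probe ids called differential-PIF.
#' @param k top-k per sign (default 5).
#' @param criterion seed on "rif1", "rif2", or "both" (default): the union
#'   of the two selections.
#' @param trIncidentOnly if TRUE keep only edges with a seed regulator
#'   endpoint.
#' @param group group tag; defaults to the tag on the edges.
#' @return a [RegulatorNetwork-class]. Node types: TR for seed regulators,
#'   DEG / PIF / DEG+PIF for partners by set membership.
#' @export
extractNetwork <- function(edges, rif, degProbes, pifProbes = character(),
                           k = 5L, criterion = c("both", "rif1", "rif2"),
                           trIncidentOnly = FALSE, group = NULL) {
  criterion <- match.arg(criterion)
  grp <- if (!is.null(group)) group
         else if (nrow(edges)) as.character(edges$group[1])
         else NA_character_
  seeds <- character()
  pick <- function(score) {
    zr <- zscoreRank(rif[[score]], ids = rif$tr, k = k)
    c(zr$topPositive, zr$topNegative)
  }
  if (criterion %in% c("both", "rif1")) seeds <- c(seeds, pick("z1"))
  if (criterion %in% c("both", "rif2")) seeds <- c(seeds, pick("z2"))
  seeds <- sort(unique(seeds))
  if (!length(seeds)) stop("empty seed regulator selection")

  targetsPool <- union(degProbes, pifProbes)
  touch <- edges$gene_a %in% seeds | edges$gene_b %in% seeds
  partners <- union(edges$gene_b[edges$gene_a %in% seeds],
                    edges$gene_a[edges$gene_b %in% seeds])
  partners <- sort(intersect(setdiff(partners, seeds), targetsPool))
  nodes <- c(seeds, partners)

  keep <- edges$gene_a %in% nodes & edges$gene_b %in% nodes
  if (trIncidentOnly) keep <- keep & touch
  ed <- edges[keep, , drop = FALSE]
  ed <- ed[order(ed$gene_a, ed$gene_b), , drop = FALSE]
  rownames(ed) <- NULL

  nodeType <- function(id) {
    if (id %in% seeds) return("TR")
    inD <- id %in% degProbes
    inP <- id %in% pifProbes
    if (inD && inP) "DEG+PIF" else if (inD) "DEG" else "PIF"
  }
  nd <- data.frame(id = nodes,
                   type = vapply(nodes, nodeType, character(1)),
                   row.names = NULL, stringsAsFactors = FALSE)
  new("RegulatorNetwork", nodes = nd, edges = ed, group = grp,
      criterion = criterion, k = as.integer(k))
}

#' Summary statistics of a regulator network
#'
#' @param net a [RegulatorNetwork-class].
#' @return list: \code{nNodes}, \code{nEdges}, \code{typeCounts} (named
#'   integer vector by node type, alphabetical), \code{degree} (named
#'   vector in node-id order), \code{degreeDistribution} (table of degree
#'   frequencies).
#' @export
networkStats <- function(net) {
  nd <- networkNodes(net)
  ed <- networkEdges(net)
  deg <- stats::setNames(integer(nrow(nd)), nd$id)
  if (nrow(ed)) {
    t1 <- table(factor(ed$gene_a, levels = nd$id))
    t2 <- table(factor(ed$gene_b, levels = nd$id))
    deg <- stats::setNames(as.integer(t1 + t2), nd$id)
  }
  tc <- table(factor(nd$type, levels = sort(unique(nd$type))))
  list(nNodes = nrow(nd), nEdges = nrow(ed),
       typeCounts = stats::setNames(as.integer(tc), names(tc)),
       degree = deg,
       degreeDistribution = table(deg))
}
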