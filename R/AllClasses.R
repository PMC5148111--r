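#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData rowData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Container for a 2x2 breed-by-altitude expression experiment
#'
#' Extends \linkS4class{SummarizedExperiment} with two assays —
#' \code{"exprs"} (log2 intensities) and \code{"flags"} (per-cell
#' present/absent detection calls) — and a column design carrying the
#' \code{breed} and \code{altitude} factors of the migrant design.
#' Probe identifiers are the row names throughout; gene symbols, where
#' available, live in \code{rowData(x)$gene} and are attached only at
#' reporting time.
#'
#' @slot .. inherited from SummarizedExperiment.
#' @seealso [MigrantArrayExperiment()] for the validated constructor,
#'   [intensities()], [detectionFlags()], [sampleDesign()], [probeGenes()],
#'   [groupLabels()].
#' @export
setClass("MigrantArrayExperiment", contains = "SummarizedExperiment")

setValidity("MigrantArrayExperiment", function(object) {
  msg <- character()
  if (!all(c("exprs", "flags") %in% assayNames(object)))
    msg <- c(msg, "assays must contain 'exprs' and 'flags'")
  else {
    fl <- assay(object, "flags")
    if (!all(fl %in% c("P", "A")))
      msg <- c(msg, "detection flags must be 'P' or 'A' with no missing cells")
  }
  cd <- colData(object)
  for (f in c("breed", "altitude")) {
    if (!f %in% colnames(cd))
      msg <- c(msg, sprintf("colData must contain a '%s' column", f))
    else if (nlevels(factor(cd[[f]])) != 2L)
      msg <- c(msg, sprintf("'%s' must have exactly 2 levels, found: %s",
                            f, paste(levels(factor(cd[[f]])), collapse = ", ")))
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate probe ids in row names")
  if (length(msg)) msg else TRUE
})

#' Construct a MigrantArrayExperiment
#'
#' @param exprs numeric probe x sample matrix of log2 intensities, with
#'   probe ids as row names and sample ids as column names.
#' @param design data.frame with columns \code{sample}, \code{breed},
#'   \code{altitude}; one row per matrix column. Breed and altitude must
#'   each have exactly two levels.
#' @param flags character matrix over \code{\{"P","A"\}} of the same shape
#'   and dimnames as \code{exprs}, or \code{NULL} in which case every cell
#'   is taken as present ("P").
#' @param probeAnnotation optional data.frame with columns \code{probe} and
#'   \code{gene} mapping probe ids to gene symbols; probes without an entry
#'   get \code{NA}.
#' @return a validated [MigrantArrayExperiment-class] object. A per-sample
#'   group code (e.g. "TH" for Tibetan/high) is derived from the initials of
#'   the breed and altitude levels and stored in \code{colData(x)$group}.
#' @examples
#' m <- matrix(rnorm(12, 10), 3, 4,
#'             dimnames = list(paste0("p", 1:3), paste0("s", 1:4)))
#' d <- data.frame(sample = colnames(m),
#'                 breed = rep(c("Tibetan", "Duroc"), each = 2),
#'                 altitude = rep(c("high", "low"), 2))
#' mae <- MigrantArrayExperiment(m, d)
#' groupLabels(mae)
#' @export
MigrantArrayExperiment <- function(exprs, design, flags = NULL,
                                   probeAnnotation = NULL) {
  exprs <- as.matrix(exprs)
  if (!is.numeric(exprs)) stop("expression matrix must be numeric")
  if (is.null(rownames(exprs)))
    stop("expression matrix must have probe ids as row names")
  if (is.null(colnames(exprs)))
    stop("expression matrix must have sample ids as column names")
  if (is.null(flags)) {
    flags <- matrix("P", nrow(exprs), ncol(exprs), dimnames = dimnames(exprs))
  } else {
    flags <- as.matrix(flags)
    if (!identical(dim(flags), dim(exprs)))
      stop(sprintf("flags matrix is %d x %d but expression is %d x %d",
                   nrow(flags), ncol(flags), nrow(exprs), ncol(exprs)))
    dimnames(flags) <- dimnames(exprs)
  }
  design <- as.data.frame(design)
  need <- c("sample", "breed", "altitude")
  if (!all(need %in% colnames(design)))
    stop("design must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(design$sample))
    stop("duplicate sample ids in design: ",
         paste(unique(design$sample[duplicated(design$sample)]), collapse = ", "))
  miss <- setdiff(colnames(exprs), design$sample)
  if (length(miss))
    stop("samples missing from design: ", paste(miss, collapse = ", "))
  design <- design[match(colnames(exprs), design$sample), , drop = FALSE]
  for (f in c("breed", "altitude")) {
    lv <- unique(as.character(design[[f]]))
    if (length(lv) != 2L)
      stop(sprintf("'%s' must have exactly 2 levels, found: %s",
                   f, paste(lv, collapse = ", ")))
  }
  breed <- factor(design$breed)
  altitude <- factor(design$altitude)
  group <- paste0(toupper(substring(as.character(breed), 1L, 1L)),
                  toupper(substring(as.character(altitude), 1L, 1L)))
  gene <- rep(NA_character_, nrow(exprs))
  if (!is.null(probeAnnotation)) {
    probeAnnotation <- as.data.frame(probeAnnotation)
    if (!all(c("probe", "gene") %in% colnames(probeAnnotation)))
      stop("probeAnnotation must have columns 'probe' and 'gene'")
    idx <- match(rownames(exprs), probeAnnotation$probe)
    gene <- as.character(probeAnnotation$gene)[idx]
  }
  se <- SummarizedExperiment(
    assays = list(exprs = exprs, flags = flags),
    colData = DataFrame(sample = design$sample, breed = breed,
                        altitude = altitude, group = group,
                        row.names = colnames(exprs)),
    rowData = DataFrame(probe = rownames(exprs), gene = gene,
                        row.names = rownames(exprs)))
  new("MigrantArrayExperiment", se)
}

#' @describeIn MigrantArrayExperiment log2 intensity matrix.
#' @param x a MigrantArrayExperiment.
#' @export
intensities <- function(x) assay(x, "exprs")

#' @describeIn MigrantArrayExperiment present/absent flag matrix.
#' @export
detectionFlags <- function(x) assay(x, "flags")

#' @describeIn MigrantArrayExperiment per-sample design as a data.frame
#'   (sample, breed, altitude, group).
#' @export
sampleDesign <- function(x) {
  as.data.frame(colData(x)[, c("sample", "breed", "altitude", "group")])
}

#' @describeIn MigrantArrayExperiment per-sample group code (e.g. "TH").
#' @export
groupLabels <- function(x) colData(x)$group

#' @describeIn MigrantArrayExperiment named probe -> gene symbol vector
#'   (NA where unannotated).
#' @export
probeGenes <- function(x) {
  g <- rowData(x)$gene
  names(g) <- rownames(x)
  g
}

setMethod("show", "MigrantArrayExperiment", function(object) {
  cat("MigrantArrayExperiment:", nrow(object), "probes x",
      ncol(object), "samples\n")
  tab <- table(groupLabels(object))
  cat("groups:", paste(sprintf("%s(n=%d)", names(tab), as.integer(tab)),
                       collapse = " "), "\n")
  nA <- sum(rowSums(detectionFlags(object) == "P") == 0L)
  cat("probes with no present call:", nA, "\n")
  invisible(NULL)
})

#' Ground truth of a simulated dataset
#'
#' Records which genes were planted as differentially expressed, which were
#' designated regulators (and their targets), and which probes were placed
#' at background, so pipeline output can be scored with [truthEval()].
#'
#' @slot deBreedGenes genes planted with a breed main effect.
#' @slot deInteractionGenes genes planted with a breed-by-altitude
#'   interaction effect (shift confined to the high-altitude cells).
#' @slot regulatorIds planted regulator genes.
#' @slot regulatorTargets named list: regulator -> character vector of
#'   target genes.
#' @slot absentProbes probe ids placed at background signal.
#' @export
setClass("SimTruth",
  representation(deBreedGenes = "character",
                 deInteractionGenes = "character",
                 regulatorIds = "character",
                 regulatorTargets = "list",
                 absentProbes = "character"))

setValidity("SimTruth", function(object) {
  msg <- character()
  if (!all(names(object@regulatorTargets) %in% object@regulatorIds))
    msg <- c(msg, "regulatorTargets keys must be a subset of regulatorIds")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", length(object@deBreedGenes), "breed-DE genes,",
      length(object@deInteractionGenes), "interaction-DE genes,",
      length(object@regulatorIds), "regulators,",
      length(object@absentProbes), "absent probes\n")
  invisible(NULL)
})

#' Accessors for SimTruth
#' @param truth a [SimTruth-class] object.
#' @return the corresponding slot.
#' @rdname SimTruth-accessors
#' @export
deBreedGenes <- function(truth) truth@deBreedGenes
#' @rdname SimTruth-accessors
#' @export
deInteractionGenes <- function(truth) truth@deInteractionGenes
#' @rdname SimTruth-accessors
#' @export
regulatorIds <- function(truth) truth@regulatorIds
#' @rdname SimTruth-accessors
#' @export
regulatorTargets <- function(truth) truth@regulatorTargets
#' @rdname SimTruth-accessors
#' @export
absentProbes <- function(truth) truth@absentProbes

#' Top-regulator co-expression subnetwork
#'
#' Nodes are the seed regulators (top-k positive and negative by RIF
#' z-score) together with their significantly co-expressed DE /
#' differential-PIF partners; edges are the retained co-expression edges
#' among those nodes within one sample group.
#'
#' @slot nodes data.frame with columns \code{id} and
#'   \code{type} (one of TR, DEG, PIF, DEG+PIF).
#' @slot edges data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{r} (correlation weight) and \code{group}.
#' @slot group sample-group tag the edges were computed in (e.g. "TH").
#' @slot criterion which RIF score seeded the network ("rif1", "rif2" or
#'   "both").
#' @slot k top-k used for seed selection.
#' @export
setClass("RegulatorNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 group = "character", criterion = "character",
                 k = "integer"))

setValidity("RegulatorNetwork", function(object) {
  msg <- character()
  if (!all(c("id", "type") %in% colnames(object@nodes)))
    msg <- c(msg, "nodes must have columns 'id' and 'type'")
  if (!all(c("gene_a", "gene_b", "r", "group") %in% colnames(object@edges)))
    msg <- c(msg, "edges must have columns gene_a, gene_b, r, group")
  if (nrow(object@edges)) {
    ep <- unique(c(object@edges$gene_a, object@edges$gene_b))
    if (!all(ep %in% object@nodes$id))
      msg <- c(msg, "orphan edge endpoints not present in node table")
    if (any(object@edges$gene_a == object@edges$gene_b))
      msg <- c(msg, "self-edges are not allowed")
  }
  if (anyDuplicated(object@nodes$id))
    msg <- c(msg, "duplicate node ids")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RegulatorNetwork", function(object) {
  cat(sprintf("RegulatorNetwork (%s, criterion=%s, k=%d): %d nodes, %d edges\n",
              object@group, object@criterion, object@k,
              nrow(object@nodes), nrow(object@edges)))
  if (nrow(object@nodes))
    print(table(object@nodes$type))
  invisible(NULL)
})

#' @describeIn RegulatorNetwork node table accessor.
#' @param x a RegulatorNetwork.
#' @export
networkNodes <- function(x) x@nodes

#' @describeIn RegulatorNetwork edge table accessor.
#' @export
networkEdges <- function(x) x@edges
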