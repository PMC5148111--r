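# full-precision numeric formatting so write -> read round-trips doubles
# exactly and repeated runs are byte-identical
.fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  dim(out) <- dim(x)
  dimnames(out) <- dimnames(x)
  out
}

.writeMatrixTsv <- function(x, path, numeric = TRUE) {
  m <- if (numeric) .fmtNum(x) else x
  df <- data.frame(probe = rownames(x), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.readMatrixTsv <- function(path, what = c("numeric", "flag")) {
  what <- match.arg(what)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (colnames(df)[1] != "probe")
    stop(sprintf("%s: first column must be 'probe'", path))
  ids <- df[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop(sprintf("%s: duplicate probe ids: %s", path,
                 paste(utils::head(dup, 5), collapse = ", ")))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  if (what == "numeric") {
    suppressWarnings(storage.mode(m) <- "double")
    if (anyNA(m)) {
      w <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop(sprintf("%s: non-numeric cell at row %s, column %s",
                   path, rownames(m)[w[1]], colnames(m)[w[2]]))
    }
  } else {
    bad <- which(!(m %in% c("P", "A")))
    if (length(bad)) {
      w <- arrayInd(bad[1], dim(m))
      stop(sprintf("%s: flag not in {P,A} at row %s, column %s",
                   path, rownames(m)[w[1]], colnames(m)[w[2]]))
    }
  }
  m
}

#' Read a dataset from its tab-separated files
#'
#' Expects an expression TSV (first column \code{probe}, one column per
#' sample), a design TSV (columns sample, breed, altitude), and optionally
#' a flags TSV of the same shape as the expression matrix (omitted: every
#' cell present) and a probe-annotation TSV (columns probe, gene).
#'
#' @param exprFile,designFile,flagsFile,annotationFile file paths;
#'   \code{flagsFile} and \code{annotationFile} may be NULL.
#' @return a validated [MigrantArrayExperiment-class].
#' @seealso [writeDataset()] for the inverse; the pair round-trips exactly.
#' @export
readDataset <- function(exprFile, designFile, flagsFile = NULL,
                        annotationFile = NULL) {
  expr <- .readMatrixTsv(exprFile, "numeric")
  flags <- NULL
  if (!is.null(flagsFile)) {
    flags <- .readMatrixTsv(flagsFile, "flag")
    if (!identical(dim(flags), dim(expr)) ||
        !identical(rownames(flags), rownames(expr)) ||
        !identical(colnames(flags), colnames(expr)))
      stop("flags file shape or ids do not match the expression file")
  }
  design <- utils::read.delim(designFile, stringsAsFactors = FALSE)
  ann <- if (!is.null(annotationFile))
    utils::read.delim(annotationFile, stringsAsFactors = FALSE)
  else NULL
  MigrantArrayExperiment(expr, design, flags = flags, probeAnnotation = ann)
}

#' Write a dataset to tab-separated files
#'
#' @param dataset a [MigrantArrayExperiment-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default "dataset").
#' @return (invisibly) named vector of the written paths: expression,
#'   flags, design, and annotation when any probe is annotated.
#' @export
writeDataset <- function(dataset, dir, prefix = "dataset") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(s) file.path(dir, paste0(prefix, "_", s, ".tsv"))
  paths <- c(expression = p("expression"), flags = p("flags"),
             design = p("design"))
  .writeMatrixTsv(intensities(dataset), paths["expression"], numeric = TRUE)
  .writeMatrixTsv(detectionFlags(dataset), paths["flags"], numeric = FALSE)
  d <- sampleDesign(dataset)[, c("sample", "breed", "altitude")]
  d$breed <- as.character(d$breed)
  d$altitude <- as.character(d$altitude)
  utils::write.table(d, paths["design"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  g <- probeGenes(dataset)
  if (any(!is.na(g))) {
    paths["annotation"] <- p("annotation")
    utils::write.table(
      data.frame(probe = names(g), gene = unname(g)),
      paths["annotation"], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' Read a transcriptional-regulator list (one symbol per line)
#'
#' @param path text file path.
#' @return unique, non-empty character vector of symbols.
#' @export
readRegulatorList <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x <- unique(x[nzchar(x)])
  if (!length(x)) stop("regulator list is empty")
  x
}

#' Read a GMT annotation file
#'
#' Standard GMT: one term per line, tab-separated as
#' \code{term <tab> description <tab> gene1 <tab> gene2 ...}.
#'
#' @param path GMT file path.
#' @return named list term -> gene vector with a \code{"descriptions"}
#'   attribute, suitable for [enrich()].
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop(sprintf("%s: line %d has fewer than 3 tab-separated fields",
                 path, bad[1]))
  ann <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(ann) <- vapply(parts, `[[`, character(1), 1L)
  attr(ann, "descriptions") <- vapply(parts, `[[`, character(1), 2L)
  ann
}

#' Write a GMT annotation file
#'
#' @param annotation named list term -> genes (optional
#'   \code{"descriptions"} attribute).
#' @param path output path.
#' @export
writeGmt <- function(annotation, path) {
  descr <- attr(annotation, "descriptions")
  if (is.null(descr)) descr <- names(annotation)
  lines <- vapply(seq_along(annotation), function(i)
    paste(c(names(annotation)[i], descr[i], annotation[[i]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
}

#' Write a regulator network for Cytoscape
#'
#' SIF: one edge per line with the relation token "co"
#' (\code{A co B}); nodes without any edge are written as bare-id lines so
#' isolated seed regulators survive the round trip. GraphML (via igraph)
#' carries the node \code{type} and the edge \code{r} weight and
#' \code{group} as attributes.
#'
#' @param net a [RegulatorNetwork-class].
#' @param path output file path.
#' @param format "sif" or "graphml".
#' @return the path, invisibly.
#' @export
writeNetwork <- function(net, path, format = c("sif", "graphml")) {
  if (!is.character(format) || !all(format %in% c("sif", "graphml")))
    stop("unknown network format: use 'sif' or 'graphml'")
  format <- match.arg(format)
  nd <- networkNodes(net)
  ed <- networkEdges(net)
  if (format == "sif") {
    lines <- character()
    if (nrow(ed))
      lines <- sprintf("%s\tco\t%s", ed$gene_a, ed$gene_b)
    lone <- setdiff(nd$id, unique(c(ed$gene_a, ed$gene_b)))
    writeLines(c(lines, lone), path)
  } else {
    g <- igraph::graph_from_data_frame(
      d = if (nrow(ed)) ed[, c("gene_a", "gene_b", "r", "group")]
          else data.frame(gene_a = character(), gene_b = character(),
                          r = numeric(), group = character()),
      directed = FALSE, vertices = nd)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a regulator network written by [writeNetwork()]
#'
#' @param path file path.
#' @param format "sif" or "graphml".
#' @param group,criterion,k metadata to stamp on the result when reading
#'   SIF (which does not carry attributes); ignored for GraphML where
#'   available attributes are restored.
#' @return a [RegulatorNetwork-class]. SIF files restore the topology only
#'   (node types default to "DEG", r to NA).
#' @export
readNetwork <- function(path, format = c("sif", "graphml"),
                        group = NA_character_, criterion = "both", k = 5L) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    isEdge <- lengths(parts) == 3L
    ed <- data.frame(gene_a = character(), gene_b = character(),
                     r = numeric(), group = character(),
                     stringsAsFactors = FALSE)
    if (any(isEdge)) {
      ep <- do.call(rbind, parts[isEdge])
      ed <- data.frame(gene_a = ep[, 1], gene_b = ep[, 3], r = NA_real_,
                       group = group, stringsAsFactors = FALSE)
    }
    lone <- unlist(parts[!isEdge])
    ids <- sort(unique(c(ed$gene_a, ed$gene_b, lone)))
    nd <- data.frame(id = ids, type = "DEG", stringsAsFactors = FALSE)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    nd <- data.frame(id = igraph::V(g)$name,
                     type = if ("type" %in%
                               igraph::vertex_attr_names(g))
                       igraph::V(g)$type else "DEG",
                     stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(g)
    ed <- data.frame(
      gene_a = if (nrow(el)) el[, 1] else character(),
      gene_b = if (nrow(el)) el[, 2] else character(),
      r = if ("r" %in% igraph::edge_attr_names(g)) igraph::E(g)$r
          else rep(NA_real_, nrow(el)),
      group = if ("group" %in% igraph::edge_attr_names(g))
        igraph::E(g)$group else rep(group, nrow(el)),
      stringsAsFactors = FALSE)
  }
  if (nrow(ed)) {
    swap <- ed$gene_a > ed$gene_b
    tmp <- ed$gene_a[swap]; ed$gene_a[swap] <- ed$gene_b[swap]
    ed$gene_b[swap] <- tmp
    ed <- ed[order(ed$gene_a, ed$gene_b), , drop = FALSE]
    rownames(ed) <- NULL
  }
  nd <- nd[order(nd$id), , drop = FALSE]
  rownames(nd) <- NULL
  grp <- if (nrow(ed) && !all(is.na(ed$group))) ed$group[1] else group
  new("RegulatorNetwork", nodes = nd, edges = ed, group = grp,
      criterion = criterion, k = as.integer(k))
}

#' Write simulation truth to JSON
#' @param truth a [SimTruth-class].
#' @param path output path.
#' @export
writeSimTruth <- function(truth, path) {
  jsonlite::write_json(
    list(deBreedGenes = deBreedGenes(truth),
         deInteractionGenes = deInteractionGenes(truth),
         regulatorIds = regulatorIds(truth),
         regulatorTargets = regulatorTargets(truth),
         absentProbes = absentProbes(truth)),
    path, pretty = TRUE)
  invisible(path)
}

#' Read simulation truth from JSON
#' @param path JSON path written by [writeSimTruth()].
#' @return a [SimTruth-class].
#' @export
readSimTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tg <- as.list(x$regulatorTargets)
  tg <- lapply(tg, as.character)
  new("SimTruth",
      deBreedGenes = as.character(x$deBreedGenes),
      deInteractionGenes = as.character(x$deInteractionGenes),
      regulatorIds = as.character(x$regulatorIds),
      regulatorTargets = tg,
      absentProbes = as.character(x$absentProbes))
}

#' Read a YAML pipeline configuration
#'
#' Flat key-value YAML; recognized keys are the arguments of [simConfig()]
#' plus \code{alpha}, \code{rMin}, \code{topK}, \code{zCut} and
#' \code{normalize} for [runPipeline()].
#'
#' @param path YAML file path.
#' @return named list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("configuration file must be a key-value mapping")
  cfg
}
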