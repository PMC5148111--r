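#' Run the full regulator-discovery pipeline
#'
#' Executes every stage in order on a simulated or supplied dataset:
#' detection filtering, optional quantile normalization, per-probe two-way
#' ANOVA with DEG selection, PIF and differential-PIF, within-group PCIT
#' edge filtering with the |r| threshold (on the DEG, differential-PIF and
#' regulator probe universe), RIF1/RIF2 scoring against the gene-collapsed
#' DEG set, top-regulator network extraction per group, and (when an
#' annotation is supplied) over-representation of the DEG gene list. Every
#' result is written as a plain-text file under \code{outDir}; outputs are
#' deterministic given the configuration seed, so repeated runs are
#' byte-identical.
#'
#' @param outDir output directory.
#' @param config a [simConfig()] used to simulate the input dataset;
#'   ignored when \code{dataset} is given.
#' @param dataset optional [MigrantArrayExperiment-class] to analyze
#'   instead of simulating.
#' @param trGenes regulator gene symbols; defaults to the simulation's
#'   planted regulators.
#' @param alpha DEG / differential-PIF FDR threshold (default 1e-4).
#' @param rMin absolute-correlation edge threshold (default 0.95).
#' @param topK regulators per sign seeding each network (default 5).
#' @param zCut z-score magnitude for the extreme-regulator counts.
#' @param normalize quantile-normalize after filtering (default TRUE).
#' @param annotation optional term -> genes list (see [readGmt()]) for the
#'   enrichment stage.
#' @param groups the two contrasted groups (default c("TH", "DH")).
#' @return (invisibly) list with the intermediate objects (\code{anova},
#'   \code{degs}, \code{pif}, \code{diffPif}, \code{edges}, \code{rif},
#'   \code{networks}, \code{enrichment}, \code{truth}) and \code{files},
#'   the named vector of written paths.
#' @export
runPipeline <- function(outDir, config = simConfig(), dataset = NULL,
                        trGenes = NULL, alpha = 1e-4, rMin = 0.95,
                        topK = 5L, zCut = 2, normalize = TRUE,
                        annotation = NULL, groups = c("TH", "DH")) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  truth <- NULL
  if (is.null(dataset)) {
    sim <- simulateDataset(config)
    dataset <- sim$dataset
    truth <- sim$truth
    if (is.null(trGenes)) trGenes <- sim$regulators
    files <- writeDataset(dataset, outDir, prefix = "input")
    files["truth"] <- file.path(outDir, "truth.json")
    writeSimTruth(truth, files["truth"])
    files["regulators"] <- file.path(outDir, "regulators.txt")
    writeLines(trGenes, files["regulators"])
  }
  if (is.null(trGenes)) stop("trGenes is required when a dataset is supplied")

  filtered <- filterExpressed(dataset)
  if (normalize) filtered <- normalizeDataset(filtered)
  files["filtered"] <- file.path(outDir, "filtered_expression.tsv")
  .writeMatrixTsv(intensities(filtered), files["filtered"])
  files["removed"] <- file.path(outDir, "removed_probes.txt")
  writeLines(metadata(filtered)$removedProbes, files["removed"])

  ann <- data.frame(probe = rownames(filtered),
                    gene = unname(probeGenes(filtered)),
                    stringsAsFactors = FALSE)
  anova <- runAnova(filtered)
  files["anova"] <- file.path(outDir, "anova.tsv")
  .writeResultTsv(anova, files["anova"])
  degs <- selectDegs(anova, alpha = alpha, annotation = ann)
  files["deg_probes"] <- file.path(outDir, "deg_probes.txt")
  writeLines(degs$probes, files["deg_probes"])
  files["deg_genes"] <- file.path(outDir, "deg_genes.txt")
  writeLines(degs$genes, files["deg_genes"])

  pif <- computePif(filtered, group1 = groups[1], group2 = groups[2])
  dpif <- differentialPif(filtered, alpha = alpha)
  pif$q_pif <- dpif$table$q_pif[match(pif$probe, dpif$table$probe)]
  files["pif"] <- file.path(outDir, "pif.tsv")
  .writeResultTsv(pif, files["pif"])
  files["diff_pif"] <- file.path(outDir, "diff_pif_probes.txt")
  writeLines(dpif$probes, files["diff_pif"])

  trProbes <- ann$probe[!is.na(ann$gene) & ann$gene %in% trGenes]
  universe <- sort(unique(c(degs$probes, dpif$probes, trProbes)))
  mat <- intensities(filtered)
  edges <- list()
  for (g in groups) {
    corr <- groupCorrelation(mat[universe, , drop = FALSE],
                             groupLabels(filtered), g)
    mask <- pcitFilter(corr)
    edges[[g]] <- thresholdEdges(corr, mask, rMin = rMin, group = g)
    files[paste0("edges_", g)] <- file.path(outDir,
                                            sprintf("edges_%s.tsv", g))
    .writeResultTsv(edges[[g]], files[paste0("edges_", g)])
  }

  deRif <- unname(degs$geneProbes)
  rif <- computeRif(mat, groupLabels(filtered), trProbes, deRif,
                    group1 = groups[1], group2 = groups[2])
  files["rif"] <- file.path(outDir, "rif.tsv")
  rifOut <- rif[order(-replace(rif$z1, is.na(rif$z1), -Inf), rif$tr), ]
  .writeResultTsv(rifOut, files["rif"])

  networks <- list()
  for (g in groups) {
    net <- extractNetwork(edges[[g]], rif, degs$probes, dpif$probes,
                          k = topK, criterion = "both", group = g)
    networks[[g]] <- net
    files[paste0("network_sif_", g)] <-
      writeNetwork(net, file.path(outDir, sprintf("network_%s.sif", g)),
                   "sif")
    files[paste0("network_graphml_", g)] <-
      writeNetwork(net, file.path(outDir, sprintf("network_%s.graphml", g)),
                   "graphml")
    st <- networkStats(net)
    files[paste0("network_stats_", g)] <-
      file.path(outDir, sprintf("network_stats_%s.json", g))
    jsonlite::write_json(
      list(group = g, nNodes = st$nNodes, nEdges = st$nEdges,
           typeCounts = as.list(st$typeCounts)),
      files[paste0("network_stats_", g)], auto_unbox = TRUE, pretty = TRUE)
  }

  enrichment <- NULL
  if (!is.null(annotation) && length(degs$genes)) {
    uniGenes <- sort(unique(ann$gene[!is.na(ann$gene)]))
    enrichment <- enrich(intersect(degs$genes, uniGenes), annotation,
                         uniGenes, overOnly = TRUE)
    files["enrichment"] <- file.path(outDir, "enrichment.tsv")
    .writeResultTsv(enrichment, files["enrichment"])
  }

  files["metadata"] <- file.path(outDir, "run_metadata.json")
  jsonlite::write_json(
    list(package = "rifnet",
         version = as.character(utils::packageVersion("rifnet")),
         rVersion = paste(R.version$major, R.version$minor, sep = "."),
         seed = if (!is.null(truth)) config$seed else NA,
         config = if (!is.null(truth)) unclass(config) else NULL,
         alpha = alpha, rMin = rMin, topK = topK, zCut = zCut,
         normalize = normalize),
    files["metadata"], auto_unbox = TRUE, pretty = TRUE)

  invisible(list(dataset = filtered, truth = truth, anova = anova,
                 degs = degs, pif = pif, diffPif = dpif, edges = edges,
                 rif = rif, networks = networks, enrichment = enrichment,
                 files = files))
}

# result tables: numerics at full precision for byte-stable reruns
.writeResultTsv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
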