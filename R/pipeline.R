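#' Build a validated pipeline configuration
#'
#' Exactly one input mode must be given: real inputs (an expression study
#' plus an interaction edge list, as objects or file paths) or
#' \code{synthetic} generation parameters. Defaults carry the workflow's
#' replication values: DEG cutoffs p < 0.01, FDR < 0.01, |logFC| >= 1, top
#' 2000; interaction score >= 0.4; whole-network thresholds degree 50,
#' stress 200000, eigenvector 0.05.
#'
#' @param expression a \linkS4class{PairedExpression}, or NULL.
#' @param exprPath,designPath,probeMapPath TSV paths used when
#'   \code{expression} is NULL.
#' @param edges an \pkg{igraph} interaction network, or NULL.
#' @param edgesPath STRING-dialect edge TSV used when \code{edges} is NULL.
#' @param synthetic list of \code{\link{generateStudy}} arguments, or NULL.
#' @param degCutoffs list with \code{pMax}, \code{fdrMax},
#'   \code{minAbsLogfc}, \code{topN}.
#' @param minScore minimum combined interaction score (0--1 scale).
#' @param primaryThresholds named thresholds for the whole-network
#'   selection, or NULL to auto-tune.
#' @param targetFraction union-fraction target used when
#'   \code{primaryThresholds} is NULL.
#' @param tuneMetrics metrics used for auto-tuned selection.
#' @param resolution,seed modularity resolution and run seed.
#' @param moduleThresholds list of named threshold vectors, one per module
#'   in module-id order, or NULL to auto-tune per module.
#' @param moduleTargetFraction union-fraction target for per-module tuning.
#' @param relVarMin coefficient-of-variation floor below which a metric is
#'   excluded within a module.
#' @param gmtPath optional GMT gene-set file for over-representation.
#' @return a validated config (class \code{commnetConfig}).
#' @export
pipelineConfig <- function(expression = NULL, exprPath = NULL,
                           designPath = NULL, probeMapPath = NULL,
                           edges = NULL, edgesPath = NULL, synthetic = NULL,
                           degCutoffs = list(pMax = 0.01, fdrMax = 0.01,
                                             minAbsLogfc = 1, topN = 2000),
                           minScore = 0.4,
                           primaryThresholds = c(degree = 50,
                                                 stress = 200000,
                                                 eigenvector = 0.05),
                           targetFraction = 0.10,
                           tuneMetrics = c("degree", "stress",
                                           "eigenvector"),
                           resolution = 1, seed = 0,
                           moduleThresholds = NULL,
                           moduleTargetFraction = 0.10, relVarMin = 0.05,
                           gmtPath = NULL) {
  haveExpr <- !is.null(expression) || !is.null(exprPath)
  haveEdges <- !is.null(edges) || !is.null(edgesPath)
  haveReal <- haveExpr && haveEdges
  if (identical(haveReal, !is.null(synthetic))) {
    stop("exactly one of {real inputs (expression + edges), synthetic ",
         "parameters} must be supplied")
  }
  defaults <- list(pMax = 0.01, fdrMax = 0.01, minAbsLogfc = 1, topN = 2000)
  degCutoffs <- utils::modifyList(defaults, as.list(degCutoffs))
  stopifnot(degCutoffs$pMax > 0, degCutoffs$pMax <= 1,
            degCutoffs$fdrMax > 0, degCutoffs$fdrMax <= 1,
            degCutoffs$minAbsLogfc >= 0, degCutoffs$topN >= 1,
            minScore >= 0, minScore <= 1, resolution > 0,
            relVarMin >= 0, targetFraction > 0, targetFraction < 1,
            moduleTargetFraction > 0, moduleTargetFraction < 1)
  structure(list(
    expression = expression, exprPath = exprPath, designPath = designPath,
    probeMapPath = probeMapPath, edges = edges, edgesPath = edgesPath,
    synthetic = synthetic, degCutoffs = degCutoffs, minScore = minScore,
    primaryThresholds = primaryThresholds,
    targetFraction = targetFraction, tuneMetrics = tuneMetrics,
    resolution = resolution, seed = as.integer(seed),
    moduleThresholds = moduleThresholds,
    moduleTargetFraction = moduleTargetFraction, relVarMin = relVarMin,
    gmtPath = gmtPath), class = "commnetConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields map directly onto \code{\link{pipelineConfig}} arguments;
#' \code{primaryThresholds} and each element of \code{moduleThresholds} are
#' YAML maps of metric -> minimum value.
#'
#' @param path YAML file.
#' @return a validated config (class \code{commnetConfig}).
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$primaryThresholds)) {
    y$primaryThresholds <- unlist(y$primaryThresholds)
  }
  if (!is.null(y$moduleThresholds)) {
    y$moduleThresholds <- lapply(y$moduleThresholds, unlist)
  }
  do.call(pipelineConfig, y)
}

allMetrics <- c("degree", "stress", "betweenness", "closeness",
                "eigenvector")

#' Run the full communicative-gene workflow
#'
#' Stage order: differential expression (moderated paired t, cutoffs,
#' probe collapse) -> DEG network construction -> component extraction (the
#' largest connected component is analyzed; smaller components are reported
#' only) -> micro-level centrality -> primary-gene selection (threshold
#' union) -> re-induction of the primary-gene network -> centrality on it ->
#' modularity optimisation (singletons excluded, reported) -> per-module
#' low-variance metric exclusion and top-gene selection -> intra-/inter-
#' module subnetworks -> optional gene-set over-representation. Every
#' artifact is a plain TSV/JSON/GraphML file; \code{manifest.json} records
#' version, seed, thresholds and per-stage counts (no timestamps, so equal
#' seeds give byte-identical manifests).
#'
#' @param config a config from \code{\link{pipelineConfig}}.
#' @param outDir run directory to create and fill.
#' @return invisibly, a list with the in-memory stage results (and the run
#'   manifest as \code{$manifest}).
#' @export
runPipeline <- function(config, outDir) {
  stopifnot(inherits(config, "commnetConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  manifest <- list(
    package = "commnet",
    version = as.character(utils::packageVersion("commnet")),
    seed = config$seed,
    parameters = list(
      degCutoffs = config$degCutoffs, minScore = config$minScore,
      primaryThresholds = as.list(config$primaryThresholds),
      targetFraction = config$targetFraction,
      resolution = config$resolution, relVarMin = config$relVarMin,
      moduleThresholds = lapply(config$moduleThresholds, as.list)),
    status = "running")
  currentStage <- "init"
  writeManifest <- function() {
    manifest$counts <- counts
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  abort <- function(e) {
    manifest$status <<- "aborted"
    manifest$failedStage <<- currentStage
    manifest$error <<- conditionMessage(e)
    writeManifest()
    stop("pipeline stage '", currentStage, "' failed: ",
         conditionMessage(e), call. = FALSE)
  }

  res <- tryCatch({
    # ---- inputs -----------------------------------------------------------
    currentStage <- "inputs"
    truth <- NULL
    if (!is.null(config$synthetic)) {
      study <- do.call(generateStudy,
                       c(config$synthetic, list(seed = config$seed)))
      expr <- study$expression; fullGraph <- study$graph
      truth <- study$truth
    } else {
      expr <- if (!is.null(config$expression)) config$expression else
        readExpressionTSV(config$exprPath, config$designPath,
                          config$probeMapPath)
      fullGraph <- if (!is.null(config$edges)) config$edges else
        readStringEdges(config$edgesPath, minScore = config$minScore)
    }
    counts$nProbes <- nrow(expr)
    counts$nSamples <- ncol(expr)
    counts$ppiNodes <- igraph::vcount(fullGraph)
    counts$ppiEdges <- igraph::ecount(fullGraph)

    # ---- differential expression -----------------------------------------
    currentStage <- "dge"
    probeTab <- moderatedPairedT(expr)
    cut <- config$degCutoffs
    degProbes <- selectDEGs(probeTab, pMax = cut$pMax, fdrMax = cut$fdrMax,
                            minAbsLogfc = cut$minAbsLogfc, topN = cut$topN)
    degGenes <- collapseProbes(degProbes, probeMap(expr))
    writeDGETSV(probeTab, file.path(outDir, "dge_probes.tsv"))
    writeDGETSV(degGenes, file.path(outDir, "degs.tsv"))
    counts$nDegProbes <- nrow(degProbes)
    counts$nDegGenes <- nrow(degGenes)

    # ---- DEG network and components --------------------------------------
    currentStage <- "network"
    degGraph <- suppressMessages(inducedSubgraph(fullGraph, degGenes$gene))
    compSummary <- summarizeComponents(degGraph)
    comps <- connectedComponents(degGraph)
    if (length(comps) == 0 || length(comps[[1]]) < 3) {
      stop("DEG network has no analyzable component")
    }
    mainGraph <- igraph::induced_subgraph(degGraph, comps[[1]])
    writeEdgesTSV(degGraph, file.path(outDir, "deg_network_edges.tsv"))
    counts$degNetworkNodes <- igraph::vcount(degGraph)
    counts$degNetworkEdges <- igraph::ecount(degGraph)
    counts$nComponents <- compSummary@nComponents
    counts$connectedNodes <- compSummary@totalConnectedNodes
    counts$mainComponentSize <- length(comps[[1]])

    # ---- micro-level centrality and primary selection ---------------------
    currentStage <- "centrality_main"
    centMain <- computeCentrality(mainGraph)
    writeCentralityTSV(centMain, file.path(outDir, "centrality_main.tsv"))

    currentStage <- "primary_selection"
    if (!is.null(config$primaryThresholds)) {
      primarySel <- selectPrimary(centMain, config$primaryThresholds)
    } else {
      tuned <- tuneThresholds(centMain, config$tuneMetrics,
                              targetFraction = config$targetFraction)
      primarySel <- tuned$selection
    }
    writeSelectionTSV(primarySel, file.path(outDir, "primary_selection.tsv"))
    counts$nPrimary <- length(combinedGenes(primarySel))

    # ---- primary-gene network --------------------------------------------
    currentStage <- "primary_network"
    pg <- suppressMessages(inducedSubgraph(fullGraph,
                                           combinedGenes(primarySel)))
    deg0 <- igraph::degree(pg)
    singletons <- sort(names(deg0)[deg0 == 0])
    pgc <- igraph::induced_subgraph(pg, names(deg0)[deg0 > 0])
    writeEdgesTSV(pg, file.path(outDir, "primary_network_edges.tsv"))
    writeGraphML(pg, file.path(outDir, "primary_network.graphml"))
    counts$primaryNetworkNodes <- igraph::vcount(pg)
    counts$primaryNetworkEdges <- igraph::ecount(pg)
    counts$primarySingletons <- length(singletons)
    counts$primaryConnectedNodes <- igraph::vcount(pgc)

    currentStage <- "centrality_primary"
    centPrim <- computeCentrality(pg)
    writeCentralityTSV(centPrim, file.path(outDir, "centrality_primary.tsv"))

    # ---- modularity -------------------------------------------------------
    currentStage <- "modularity"
    partition <- louvain(pgc, resolution = config$resolution,
                         seed = config$seed)
    writePartitionTSV(partition, file.path(outDir, "partition.tsv"))
    modules <- moduleMembers(partition)
    counts$nModules <- length(modules)
    counts$moduleSizes <- vapply(modules, length, integer(1))
    counts$modularityQ <- modularityQ(partition)

    # ---- per-module top communicative genes -------------------------------
    currentStage <- "module_selection"
    topSel <- vector("list", length(modules))
    excludedMetrics <- vector("list", length(modules))
    for (k in seq_along(modules)) {
      members <- modules[[k]]
      modTable <- centPrim[centPrim$node %in% members,
                           c("node", allMetrics), drop = FALSE]
      if (nrow(modTable) < 2) {
        topSel[[k]] <- methods::new("SelectionResult",
          perMetric = list(), combined = sort(members),
          thresholds = numeric(0), graphSize = nrow(modTable))
        excludedMetrics[[k]] <- character(0)
        next
      }
      lowVar <- lowVarianceMetrics(modTable, relVarMin = config$relVarMin)
      usable <- setdiff(allMetrics, lowVar)
      excludedMetrics[[k]] <- lowVar
      spec <- NULL
      if (!is.null(config$moduleThresholds) &&
          length(config$moduleThresholds) >= k) {
        spec <- config$moduleThresholds[[k]]
        dropped <- intersect(names(spec), lowVar)
        if (length(dropped)) {
          message("module ", k, ": dropping low-variance metric(s) ",
                  paste(dropped, collapse = ", "))
          spec <- spec[setdiff(names(spec), dropped)]
        }
      }
      if (is.null(spec) || length(spec) == 0) {
        spec <- tuneThresholds(modTable, usable,
                               targetFraction =
                                 config$moduleTargetFraction)$thresholds
      }
      topSel[[k]] <- selectTopInModule(modTable, spec)
      writeSelectionTSV(topSel[[k]],
                        file.path(outDir, sprintf("module%d_top.tsv", k)))
    }
    counts$topCounts <- vapply(topSel,
                               function(s) length(combinedGenes(s)),
                               integer(1))
    counts$excludedMetrics <- excludedMetrics

    # ---- subnetworks ------------------------------------------------------
    currentStage <- "subnets"
    for (k in seq_along(modules)) {
      sub <- intraModuleSubnet(pg, combinedGenes(topSel[[k]]),
                               modules[[k]])
      writeEdgesTSV(sub, file.path(outDir,
                                   sprintf("module%d_subnet_edges.tsv", k)))
      writeGraphML(sub, file.path(outDir,
                                  sprintf("module%d_subnet.graphml", k)))
    }
    interSub <- NULL
    if (length(modules) >= 2) {
      interSub <- interModuleSubnet(pg, combinedGenes(topSel[[1]]),
                                    combinedGenes(topSel[[2]]))
      el <- igraph::as_data_frame(interSub, what = "edges")
      writeTSV(el, file.path(outDir, "inter_module_subnet_edges.tsv"))
      counts$interEdgeClasses <- if (nrow(el)) as.list(table(el$class))
                                 else list()
    }

    # ---- over-representation ---------------------------------------------
    currentStage <- "enrichment"
    oraTables <- NULL
    if (!is.null(config$gmtPath)) {
      collection <- readGmt(config$gmtPath)
      bg <- igraph::V(pg)$name
      oraTables <- lapply(seq_along(modules), function(k) {
        tab <- oraHypergeometric(intersect(modules[[k]], bg), collection,
                                 bg)
        writeTSV(tab, file.path(outDir,
                                sprintf("enrichment_module%d.tsv", k)))
        tab
      })
    }

    currentStage <- "finalize"
    manifest$status <- "complete"
    writeManifest()
    invisible(list(
      expression = expr, fullGraph = fullGraph, truth = truth,
      probeTable = probeTab, degGenes = degGenes, degGraph = degGraph,
      componentSummary = compSummary, mainGraph = mainGraph,
      centralityMain = centMain, primarySelection = primarySel,
      primaryGraph = pg, primarySingletons = singletons,
      centralityPrimary = centPrim, partition = partition,
      modules = modules, topSelections = topSel, interSubnet = interSub,
      enrichment = oraTables, manifest = manifest, counts = counts,
      outDir = outDir))
  }, error = abort)
  res
}

#' Summarize a pipeline run directory
#'
#' Produces a human-readable markdown summary of a run: per-stage counts,
#' component profile, module sizes with up-/down-regulated member counts,
#' and the per-module top communicative gene tables. Missing artifacts of an
#' aborted run are listed.
#'
#' @param runDir directory written by \code{\link{runPipeline}}.
#' @param file optional path to also write the report to (default
#'   \code{report.md} in \code{runDir}; NULL suppresses writing).
#' @return the report, invisibly, as a character vector of lines.
#' @export
pipelineReport <- function(runDir, file = file.path(runDir, "report.md")) {
  manifestPath <- file.path(runDir, "manifest.json")
  if (!file.exists(manifestPath)) stop("no manifest.json in ", runDir)
  man <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
  cnt <- man$counts
  lines <- c("# Communicative-gene workflow report", "",
             paste0("Package commnet ", man$version, ", seed ", man$seed,
                    ", status: ", man$status))
  if (identical(man$status, "aborted")) {
    lines <- c(lines, paste0("Run aborted at stage: ", man$failedStage),
               paste0("Error: ", man$error))
  }
  lines <- c(lines, "", "## Stage counts", "")
  for (nm in names(cnt)) {
    val <- cnt[[nm]]
    if (is.list(val)) val <- unlist(val)
    lines <- c(lines, paste0("- ", nm, ": ", paste(val, collapse = ", ")))
  }

  expected <- c("degs.tsv", "centrality_main.tsv", "primary_selection.tsv",
                "partition.tsv")
  missing <- expected[!file.exists(file.path(runDir, expected))]
  if (length(missing)) {
    lines <- c(lines, "", "## Missing artifacts", "",
               paste0("- ", missing))
  }

  partPath <- file.path(runDir, "partition.tsv")
  degPath <- file.path(runDir, "degs.tsv")
  if (file.exists(partPath) && file.exists(degPath)) {
    part <- readTSV(partPath)
    degs <- readDGETSV(degPath)
    lines <- c(lines, "", "## Modules (up/down member counts)", "")
    for (k in sort(unique(part$module))) {
      members <- part$node[part$module == k]
      lfc <- degs$logFC[match(members, degs$gene)]
      lines <- c(lines, sprintf(
        "- module %d: %d genes (%d up, %d down)", k + 1L, length(members),
        sum(lfc > 0, na.rm = TRUE), sum(lfc < 0, na.rm = TRUE)))
      topPath <- file.path(runDir, sprintf("module%d_top.tsv", k + 1L))
      if (file.exists(topPath)) {
        top <- readTSV(topPath)
        lines <- c(lines, sprintf("    top communicative genes (%d): %s",
                                  nrow(top),
                                  paste(top$node, collapse = ", ")))
      }
    }
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
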