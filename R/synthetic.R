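#' Generate a paired two-condition expression matrix with known truth
#'
#' Emulates a normalized, log2-scale microarray study with a paired
#' lesional/non-lesional design: per-gene baselines on the log2 scale,
#' probe-specific offsets (several probes may map to one gene), a shared
#' patient effect for the two samples of each patient, and i.i.d. Gaussian
#' noise. A chosen fraction of genes carries a true log2 fold change added to
#' every probe of the gene in the lesional samples.
#'
#' Defaults mirror a moderate-to-severe psoriasis microarray study: 85
#' lesional/non-lesional pairs, 2000 measured genes, effects of 1--3 log2
#' units in either direction on 20\% of genes, residual noise sd 0.5.
#'
#' @param nGenes number of genes (ignored when \code{genes} is supplied).
#' @param nPairs number of patients; each contributes one NL and one LL
#'   sample.
#' @param deFraction fraction of genes given a nonzero effect (ignored when
#'   \code{deGenes} is supplied).
#' @param effectRange interval of absolute log2 fold changes; effects are
#'   drawn uniformly from it with random sign.
#' @param noiseSd residual noise standard deviation (log2 units), > 0.
#' @param probesPerGene distribution of probes per gene: either a single
#'   integer (fixed count) or a named probability vector whose names are
#'   probe counts, e.g. \code{c("1" = .7, "2" = .2, "3" = .1)}.
#' @param seed integer seed; all randomness flows through it.
#' @param genes optional character vector of gene symbols to use.
#' @param deGenes optional explicit set of differential genes.
#' @param effects optional named vector of true log2 fold changes for
#'   \code{deGenes} (drawn from \code{effectRange} when NULL).
#' @param baselineMean,baselineSd mean/sd of per-gene baseline log2
#'   intensity.
#' @param probeOffsetSd sd of the probe-specific additive offset.
#' @param patientSd sd of the per-patient effect shared by both samples.
#' @return list with elements \code{expression}
#'   (\linkS4class{PairedExpression}) and \code{truth}
#'   (\linkS4class{SyntheticTruth}).
#' @export
generateExpression <- function(nGenes = 2000, nPairs = 85, deFraction = 0.2,
                               effectRange = c(1, 3), noiseSd = 0.5,
                               probesPerGene = c("1" = 0.7, "2" = 0.2,
                                                 "3" = 0.1),
                               seed = 0, genes = NULL, deGenes = NULL,
                               effects = NULL, baselineMean = 8,
                               baselineSd = 2, probeOffsetSd = 0.25,
                               patientSd = 1) {
  if (is.null(genes)) {
    nGenes <- checkCount(nGenes, "nGenes")
    genes <- sprintf("g%05d", seq_len(nGenes))
  } else {
    genes <- as.character(genes)
    nGenes <- length(genes)
    if (nGenes < 1) stop("'genes' must be non-empty")
  }
  nPairs <- checkCount(nPairs, "nPairs", min = 2)
  deFraction <- checkFraction(deFraction, "deFraction")
  if (!is.finite(noiseSd) || noiseSd <= 0) stop("'noiseSd' must be > 0")

  withSeed(seed, {
    # differential genes and their true effects
    if (is.null(deGenes)) {
      nDe <- round(deFraction * nGenes)
      deGenes <- sort(sample(genes, nDe))
    } else {
      deGenes <- as.character(deGenes)
      if (!all(deGenes %in% genes)) stop("'deGenes' must be a subset of genes")
    }
    if (is.null(effects)) {
      effects <- stats::setNames(
        sample(c(-1, 1), length(deGenes), replace = TRUE) *
          stats::runif(length(deGenes), effectRange[1], effectRange[2]),
        deGenes)
    } else {
      if (!all(deGenes %in% names(effects))) {
        stop("'effects' must be named and cover deGenes")
      }
      effects <- effects[deGenes]
    }
    effectAll <- stats::setNames(numeric(nGenes), genes)
    effectAll[names(effects)] <- effects

    # probes per gene
    if (length(probesPerGene) == 1 && is.null(names(probesPerGene))) {
      counts <- rep(as.integer(probesPerGene), nGenes)
    } else {
      sizes <- as.integer(names(probesPerGene))
      counts <- sample(sizes, nGenes, replace = TRUE, prob = probesPerGene)
      if (max(sizes[probesPerGene > 0]) > 1 && all(counts == 1)) {
        counts[1] <- 2L  # guarantee a nontrivial probe collapse
      }
    }
    geneOfProbe <- rep(genes, counts)
    probeIds <- unlist(lapply(seq_len(nGenes), function(i) {
      sprintf("%s_p%02d", genes[i], seq_len(counts[i]))
    }), use.names = FALSE)
    nProbes <- length(probeIds)

    baseline <- stats::setNames(
      stats::rnorm(nGenes, baselineMean, baselineSd), genes)
    probeBase <- baseline[geneOfProbe] +
      stats::rnorm(nProbes, 0, probeOffsetSd)

    patients <- sprintf("P%03d", seq_len(nPairs))
    samples <- as.vector(rbind(paste0(patients, "_NL"),
                               paste0(patients, "_LL")))
    condition <- rep(c("NL", "LL"), nPairs)
    patientOfSample <- rep(patients, each = 2)
    patientEffect <- stats::setNames(stats::rnorm(nPairs, 0, patientSd),
                                     patients)

    mat <- matrix(probeBase, nProbes, 2 * nPairs) +
      matrix(patientEffect[patientOfSample], nProbes, 2 * nPairs,
             byrow = TRUE) +
      outer(effectAll[geneOfProbe], as.numeric(condition == "LL")) +
      matrix(stats::rnorm(nProbes * 2 * nPairs, 0, noiseSd),
             nProbes, 2 * nPairs)
    dimnames(mat) <- list(probeIds, samples)

    design <- data.frame(sample = samples, patient = patientOfSample,
                         condition = condition, stringsAsFactors = FALSE)
    expr <- PairedExpression(mat, design,
                             data.frame(probe = probeIds, gene = geneOfProbe,
                                        stringsAsFactors = FALSE))
    truth <- methods::new("SyntheticTruth",
      deGenes = deGenes,
      effectSizes = effectAll,
      moduleAssignment = stats::setNames(rep("background", nGenes), genes),
      hubGenes = character(0))
    list(expression = expr, truth = truth)
  })
}

#' Generate an undirected simple PPI-style graph with planted structure
#'
#' Builds a planted-partition graph: two dense modules with within-module
#' edge probability \code{pIn}, a sparse background with cross/background
#' edge probability \code{pOut}, hub nodes receiving extra random
#' attachments, and small disconnected 2--3-node components appended (two-node
#' components are single edges, three-node components are paths).
#'
#' Defaults mirror the study conditions this package emulates: module sizes
#' 86 and 63, a 1445-node main part, and 17 small components (15 two-node,
#' 2 three-node), i.e. 1481 connected nodes in 18 components when the main
#' part is connected.
#'
#' @param moduleSizes integer pair: sizes of the two planted modules (>= 3).
#' @param nBackground number of background nodes in the main part.
#' @param pIn within-module edge probability; must exceed \code{pOut}.
#' @param pOut background / cross-module edge probability.
#' @param nHubs number of hub nodes (sampled from module members).
#' @param hubExtraDegree extra random attachments given to each hub.
#' @param nSmallComponents number of small disconnected components;
#'   \code{round(2/17 * n)} of them are 3-node paths, the rest 2-node edges.
#' @param seed integer seed.
#' @param genePrefix prefix for generated gene symbols.
#' @return list with elements \code{graph} (an \pkg{igraph} object with named
#'   vertices) and \code{truth} (\linkS4class{SyntheticTruth}).
#' @export
generatePPI <- function(moduleSizes = c(86, 63), nBackground = 1296,
                        pIn = 0.3, pOut = 0.005, nHubs = 10,
                        hubExtraDegree = 50, nSmallComponents = 17,
                        seed = 0, genePrefix = "g") {
  if (length(moduleSizes) != 2 || any(moduleSizes < 3)) {
    stop("'moduleSizes' must be two module sizes >= 3")
  }
  if (!(pIn > pOut)) {
    stop("'pIn' must exceed 'pOut' (planted structure unidentifiable)")
  }
  pIn <- checkFraction(pIn, "pIn"); pOut <- checkFraction(pOut, "pOut")
  nBackground <- checkCount(nBackground, "nBackground", min = 0)
  nHubs <- checkCount(nHubs, "nHubs", min = 0)
  hubExtraDegree <- checkCount(hubExtraDegree, "hubExtraDegree", min = 0)
  nSmallComponents <- checkCount(nSmallComponents, "nSmallComponents",
                                 min = 0)

  n1 <- as.integer(moduleSizes[1]); n2 <- as.integer(moduleSizes[2])
  nMain <- n1 + n2 + nBackground
  nThree <- round(2 / 17 * nSmallComponents)
  smallSizes <- c(rep(2L, nSmallComponents - nThree), rep(3L, nThree))
  nTotal <- nMain + sum(smallSizes)
  nodes <- sprintf("%s%05d", genePrefix, seq_len(nTotal))
  block <- c(rep(1L, n1), rep(2L, n2), rep(0L, nBackground),
             rep(0L, sum(smallSizes)))

  withSeed(seed, {
    # main-part edges by planted-partition sampling over all pairs
    pairIdx <- which(upper.tri(matrix(FALSE, nMain, nMain)))
    r <- ((pairIdx - 1L) %% nMain) + 1L
    cc <- ((pairIdx - 1L) %/% nMain) + 1L
    p <- ifelse(block[r] > 0L & block[r] == block[cc], pIn, pOut)
    keep <- stats::runif(length(pairIdx)) < p
    ei <- r[keep]; ej <- cc[keep]

    # hubs get extra attachments to non-neighbours in the main part
    hubs <- integer(0)
    if (nHubs > 0) {
      hubs <- sort(sample(seq_len(n1 + n2), min(nHubs, n1 + n2)))
      for (h in hubs) {
        nbrs <- c(ej[ei == h], ei[ej == h])
        cand <- setdiff(seq_len(nMain), c(h, nbrs))
        extra <- sample(cand, min(hubExtraDegree, length(cand)))
        ei <- c(ei, pmin(h, extra)); ej <- c(ej, pmax(h, extra))
      }
    }

    # small disconnected components wired as edges / paths
    nxt <- nMain
    for (s in smallSizes) {
      ids <- nxt + seq_len(s)
      ei <- c(ei, ids[-s]); ej <- c(ej, ids[-1])
      nxt <- nxt + s
    }

    g <- igraph::graph_from_data_frame(
      data.frame(from = nodes[ei], to = nodes[ej],
                 stringsAsFactors = FALSE),
      directed = FALSE, vertices = nodes)
    g <- igraph::simplify(g)

    truth <- methods::new("SyntheticTruth",
      deGenes = character(0),
      effectSizes = stats::setNames(numeric(nTotal), nodes),
      moduleAssignment = stats::setNames(
        c("background", "module1", "module2")[block + 1L], nodes),
      hubGenes = nodes[hubs])
    list(graph = g, truth = truth)
  })
}

#' Generate a coherent expression + network study
#'
#' Couples \code{\link{generatePPI}} and \code{\link{generateExpression}} so
#' that every network gene is measured on the array and carries a true
#' effect (network genes are, by construction, the differential ones), with
#' per-module effect signs mirroring mostly-upregulated cell-cycle-like and
#' mixed immune-like modules. Extra measured genes outside the network are
#' differential at rate \code{deExtraFraction}.
#'
#' @param nGenes total measured genes (must cover the network nodes).
#' @param nPairs number of patients.
#' @param upFractionModule1,upFractionModule2 fraction of module genes with a
#'   positive effect sign (defaults 81/86 and 43/63).
#' @param deExtraFraction differential fraction among non-network genes.
#' @param ppiArgs list of arguments forwarded to \code{\link{generatePPI}}.
#' @param exprArgs list of arguments forwarded to
#'   \code{\link{generateExpression}}.
#' @param effectRange interval of absolute log2 fold changes.
#' @param seed integer seed (network and expression derive sub-seeds from
#'   it).
#' @return list with elements \code{expression}, \code{graph}, \code{truth}.
#' @export
generateStudy <- function(nGenes = 2000, nPairs = 85,
                          upFractionModule1 = 81 / 86,
                          upFractionModule2 = 43 / 63,
                          deExtraFraction = 0.05, effectRange = c(1, 3),
                          ppiArgs = list(), exprArgs = list(), seed = 0) {
  ppi <- do.call(generatePPI, c(ppiArgs, list(seed = seed + 1L)))
  ppiGenes <- igraph::V(ppi$graph)$name
  if (nGenes < length(ppiGenes)) {
    stop("'nGenes' must cover the ", length(ppiGenes), " network genes")
  }
  extraGenes <- sprintf("x%05d", seq_len(nGenes - length(ppiGenes)))
  genes <- c(ppiGenes, extraGenes)

  mods <- moduleAssignment(ppi$truth)
  effects <- withSeed(seed + 2L, {
    deExtra <- sort(sample(extraGenes,
                           round(deExtraFraction * length(extraGenes))))
    de <- c(ppiGenes, deExtra)
    mag <- stats::runif(length(de), effectRange[1], effectRange[2])
    sgn <- numeric(length(de))
    for (i in seq_along(de)) {
      m <- if (de[i] %in% names(mods)) mods[[de[i]]] else "background"
      pUp <- switch(m, module1 = upFractionModule1,
                    module2 = upFractionModule2, 0.5)
      sgn[i] <- if (stats::runif(1) < pUp) 1 else -1
    }
    stats::setNames(sgn * mag, de)
  })

  ex <- do.call(generateExpression,
                c(exprArgs,
                  list(genes = genes, nPairs = nPairs,
                       deGenes = names(effects), effects = effects,
                       effectRange = effectRange, seed = seed + 3L)))

  assign2 <- stats::setNames(rep("background", length(genes)), genes)
  assign2[names(mods)] <- mods
  truth <- methods::new("SyntheticTruth",
    deGenes = sort(names(effects)),
    effectSizes = effectSizes(ex$truth),
    moduleAssignment = assign2,
    hubGenes = hubGenes(ppi$truth))
  list(expression = ex$expression, graph = ppi$graph, truth = truth)
}

#' Write a synthetic study to plain-text fixture files
#'
#' Generates a coherent study with \code{\link{generateStudy}} and writes:
#' \code{expression.tsv} (probe by sample log2 matrix), \code{design.tsv}
#' (sample, patient:condition), \code{probe_map.tsv} (probe, gene),
#' \code{edges.tsv} (STRING-dialect edge list), \code{truth.tsv}
#' (gene, effect, module, is_hub, in_network) and \code{manifest.json}.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer seed.
#' @param ... forwarded to \code{\link{generateStudy}}.
#' @return data.frame manifest (file, rows), invisibly the study is also
#'   attached as attribute \code{"study"}.
#' @export
writeFixtureBundle <- function(outDir, seed = 0, ...) {
  ok <- dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  study <- generateStudy(seed = seed, ...)

  mat <- SummarizedExperiment::assay(study$expression)
  exprDf <- data.frame(probe = rownames(mat),
                       signif(mat, 7), check.names = FALSE)
  des <- pairedDesign(study$expression)
  designDf <- data.frame(sample = des$sample,
                         group = paste0(des$patient, ":", des$condition))
  pm <- probeMap(study$expression)
  mapDf <- data.frame(probe = names(pm), gene = unname(pm))
  el <- igraph::as_data_frame(study$graph, what = "edges")
  edgeDf <- data.frame(node1 = el$from, node2 = el$to, combined_score = 900L)
  tr <- study$truth
  genes <- names(effectSizes(tr))
  truthDf <- data.frame(
    gene = genes,
    effect = unname(effectSizes(tr)),
    module = unname(moduleAssignment(tr)[genes]),
    is_hub = genes %in% hubGenes(tr),
    in_network = genes %in% igraph::V(study$graph)$name)

  files <- list(expression.tsv = exprDf, design.tsv = designDf,
                probe_map.tsv = mapDf, edges.tsv = edgeDf,
                truth.tsv = truthDf)
  for (f in names(files)) writeTSV(files[[f]], file.path(outDir, f))
  manifest <- data.frame(file = names(files),
                         rows = vapply(files, nrow, integer(1)),
                         row.names = NULL)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  attr(manifest, "study") <- study
  invisible(manifest)
}

#' Read a fixture bundle back into memory
#'
#' Inverse of \code{\link{writeFixtureBundle}}: rebuilds the
#' \linkS4class{PairedExpression}, the network (including any isolated
#' nodes, recovered from \code{truth.tsv}) and the
#' \linkS4class{SyntheticTruth}.
#'
#' @param dir directory written by \code{\link{writeFixtureBundle}}.
#' @return list with elements \code{expression}, \code{graph}, \code{truth}.
#' @export
readFixtureBundle <- function(dir) {
  expr <- readExpressionTSV(file.path(dir, "expression.tsv"),
                            file.path(dir, "design.tsv"),
                            file.path(dir, "probe_map.tsv"))
  truthDf <- readTSV(file.path(dir, "truth.tsv"))
  g <- readStringEdges(file.path(dir, "edges.tsv"), minScore = 0)
  isolated <- setdiff(truthDf$gene[truthDf$in_network],
                      igraph::V(g)$name)
  if (length(isolated)) g <- igraph::add_vertices(g, length(isolated),
                                                  name = isolated)
  truth <- methods::new("SyntheticTruth",
    deGenes = sort(truthDf$gene[truthDf$effect != 0]),
    effectSizes = stats::setNames(truthDf$effect, truthDf$gene),
    moduleAssignment = stats::setNames(truthDf$module, truthDf$gene),
    hubGenes = truthDf$gene[truthDf$is_hub])
  list(expression = expr, graph = g, truth = truth)
}
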