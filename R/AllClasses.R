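#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Ground truth of a synthetic study
#'
#' Records the generative truth behind a synthetic expression matrix and/or
#' interaction network: which genes carry a true effect and of what size,
#' which planted module each gene belongs to, and which genes were wired as
#' hubs.
#'
#' @slot deGenes character vector of genes with a nonzero true log2 fold
#'   change.
#' @slot effectSizes named numeric vector, one entry per generated gene,
#'   giving the true log2 fold change (0 for null genes).
#' @slot moduleAssignment named character vector mapping every gene to one of
#'   \code{"module1"}, \code{"module2"} or \code{"background"}.
#' @slot hubGenes character vector of genes wired with elevated degree.
#'
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(
    deGenes = "character",
    effectSizes = "numeric",
    moduleAssignment = "character",
    hubGenes = "character"
  )
)

setValidity("SyntheticTruth", function(object) {
  genes <- names(object@effectSizes)
  msg <- character(0)
  if (is.null(genes) || anyDuplicated(genes)) {
    msg <- c(msg, "effectSizes must be uniquely named by gene")
  }
  if (!all(object@deGenes %in% genes)) {
    msg <- c(msg, "deGenes must be a subset of the generated genes")
  }
  if (!all(object@hubGenes %in% names(object@moduleAssignment))) {
    msg <- c(msg, "hubGenes must be a subset of the generated genes")
  }
  if (!all(object@moduleAssignment %in%
           c("module1", "module2", "background"))) {
    msg <- c(msg, "moduleAssignment values must be module1/module2/background")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn SyntheticTruth genes with a nonzero true effect
#' @param x a \code{SyntheticTruth}
#' @export
deGenes <- function(x) x@deGenes

#' @describeIn SyntheticTruth named vector of true log2 fold changes
#' @export
effectSizes <- function(x) x@effectSizes

#' @describeIn SyntheticTruth named gene-to-module mapping
#' @export
moduleAssignment <- function(x) x@moduleAssignment

#' @describeIn SyntheticTruth genes wired with elevated degree
#' @export
hubGenes <- function(x) x@hubGenes

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", length(object@effectSizes), "genes;",
      length(object@deGenes), "differential;",
      sum(object@moduleAssignment != "background"), "in planted modules;",
      length(object@hubGenes), "hubs\n")
})

#' Paired two-condition expression matrix
#'
#' A \linkS4class{SummarizedExperiment} holding probe-by-sample log2
#' intensities under a paired design: every patient contributes exactly one
#' non-lesional (\code{NL}) and one lesional (\code{LL}) sample. Row metadata
#' carries the probe-to-gene mapping (many probes per gene allowed).
#'
#' @exportClass PairedExpression
setClass("PairedExpression", contains = "SummarizedExperiment")

setValidity("PairedExpression", function(object) {
  cd <- SummarizedExperiment::colData(object)
  rd <- SummarizedExperiment::rowData(object)
  msg <- character(0)
  if (!all(c("patient", "condition") %in% colnames(cd))) {
    msg <- c(msg, "colData must have 'patient' and 'condition' columns")
  } else {
    if (!all(cd$condition %in% c("NL", "LL"))) {
      msg <- c(msg, "condition must be 'NL' or 'LL'")
    } else {
      tab <- table(cd$patient, cd$condition)
      if (!(all(tab == 1) && ncol(tab) == 2)) {
        bad <- rownames(tab)[rowSums(tab != 1) > 0]
        msg <- c(msg, paste0("unpaired patients: ",
                             paste(bad, collapse = ", ")))
      }
    }
  }
  if (!"gene" %in% colnames(rd)) {
    msg <- c(msg, "rowData must have a 'gene' column")
  }
  a <- SummarizedExperiment::assay(object)
  if (length(a) && !all(is.finite(a))) {
    msg <- c(msg, "all intensities must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PairedExpression object
#'
#' @param values numeric matrix of log2 intensities, rows = probes (rownames
#'   required), columns = samples (colnames required).
#' @param design data.frame with columns \code{sample}, \code{patient},
#'   \code{condition} (one row per column of \code{values}).
#' @param probeMap data.frame with columns \code{probe}, \code{gene} covering
#'   every row of \code{values}, or a named character vector (names = probes).
#' @return a \linkS4class{PairedExpression}
#' @export
PairedExpression <- function(values, design, probeMap) {
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must have probe rownames and sample colnames")
  }
  map <- asProbeMap(probeMap)
  missing <- setdiff(rownames(values), names(map))
  if (length(missing)) {
    stop("probes missing from probeMap: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  design <- as.data.frame(design)
  rownames(design) <- design$sample
  design <- design[colnames(values), , drop = FALSE]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = values),
    rowData = DataFrame(probe = rownames(values),
                        gene = unname(map[rownames(values)]),
                        row.names = rownames(values)),
    colData = DataFrame(design, row.names = design$sample)
  )
  methods::new("PairedExpression", se)
}

# normalise a probe map (data.frame or named vector) to a named character
asProbeMap <- function(probeMap) {
  if (is.data.frame(probeMap)) {
    stats::setNames(as.character(probeMap$gene), as.character(probeMap$probe))
  } else {
    if (is.null(names(probeMap))) stop("probeMap vector must be named by probe")
    stats::setNames(as.character(probeMap), names(probeMap))
  }
}

#' @describeIn PairedExpression the probe-to-gene map as a named character
#'   vector
#' @param x a \code{PairedExpression}
#' @export
probeMap <- function(x) {
  rd <- SummarizedExperiment::rowData(x)
  stats::setNames(as.character(rd$gene), rownames(x))
}

#' @describeIn PairedExpression the sample design as a data.frame with
#'   columns sample, patient, condition
#' @export
pairedDesign <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  data.frame(sample = rownames(cd), patient = cd$patient,
             condition = cd$condition, row.names = NULL,
             stringsAsFactors = FALSE)
}

setMethod("show", "PairedExpression", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("PairedExpression:", nrow(object), "probes x", ncol(object),
      "samples (", length(unique(cd$patient)), "patients, paired NL/LL );",
      length(unique(SummarizedExperiment::rowData(object)$gene)), "genes\n")
})

#' Node partition from modularity optimisation
#'
#' @slot membership named integer vector mapping every node to a module id;
#'   ids are contiguous from 0, numbered by decreasing module size (ties by
#'   lexicographically smallest member).
#' @slot q modularity score of the partition at the run's resolution.
#' @slot resolution resolution parameter used.
#' @slot seed integer seed that fixed the node sweep order.
#'
#' @exportClass ModulePartition
setClass("ModulePartition",
  representation(membership = "integer", q = "numeric",
                 resolution = "numeric", seed = "integer")
)

setValidity("ModulePartition", function(object) {
  ids <- sort(unique(object@membership))
  msg <- character(0)
  if (is.null(names(object@membership))) {
    msg <- c(msg, "membership must be named by node")
  }
  if (length(ids) && !identical(ids, seq(0L, max(ids)))) {
    msg <- c(msg, "module ids must be contiguous from 0")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ModulePartition named node-to-module assignment (ids from 0)
#' @param x a \code{ModulePartition}
#' @export
nodeModules <- function(x) x@membership

#' @describeIn ModulePartition the modularity score Q of the partition
#' @export
modularityQ <- function(x) x@q

#' @describeIn ModulePartition list of node-name vectors, one per module,
#'   in module-id order
#' @export
moduleMembers <- function(x) {
  ids <- sort(unique(x@membership))
  lapply(ids, function(i) sort(names(x@membership)[x@membership == i]))
}

setMethod("show", "ModulePartition", function(object) {
  sizes <- table(object@membership)
  cat("ModulePartition:", length(object@membership), "nodes in",
      length(sizes), "modules (sizes:",
      paste(as.integer(sizes), collapse = ", "),
      "); Q =", format(object@q, digits = 4),
      "at resolution", object@resolution, "\n")
})

#' Result of a centrality-threshold gene selection
#'
#' @slot perMetric named list of character vectors: nodes meeting each
#'   metric's threshold (inclusive \code{>=}).
#' @slot combined union of the per-metric sets.
#' @slot thresholds the named thresholds applied.
#' @slot graphSize number of nodes in the table the selection ran on.
#'
#' @exportClass SelectionResult
setClass("SelectionResult",
  representation(perMetric = "list", combined = "character",
                 thresholds = "numeric", graphSize = "integer")
)

setValidity("SelectionResult", function(object) {
  u <- sort(unique(as.character(unlist(object@perMetric,
                                       use.names = FALSE))))
  if (!identical(sort(object@combined), u)) {
    return("combined must equal the union of the per-metric sets")
  }
  TRUE
})

#' @describeIn SelectionResult the union of the per-metric selections
#' @param x a \code{SelectionResult}
#' @export
combinedGenes <- function(x) x@combined

#' @describeIn SelectionResult named list of per-metric selected node sets
#' @export
metricGenes <- function(x) x@perMetric

#' @describeIn SelectionResult per-metric selection counts
#' @export
selectionCounts <- function(x) {
  vapply(x@perMetric, length, integer(1))
}

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult on", object@graphSize, "nodes:\n")
  for (m in names(object@perMetric)) {
    cat(sprintf("  %-12s >= %-10g : %d nodes\n", m, object@thresholds[[m]],
                length(object@perMetric[[m]])))
  }
  cat("  combined (union):", length(object@combined), "nodes\n")
})

#' Connected-component profile of a graph
#'
#' @slot nComponents number of connected components.
#' @slot sizeHistogram named integer vector: component size -> count.
#' @slot largestSize size of the largest component (0 for an empty graph).
#' @slot totalConnectedNodes nodes lying in components of size >= 2.
#' @slot nSingletons isolated nodes.
#'
#' @exportClass ComponentSummary
setClass("ComponentSummary",
  representation(nComponents = "integer", sizeHistogram = "integer",
                 largestSize = "integer", totalConnectedNodes = "integer",
                 nSingletons = "integer")
)

setValidity("ComponentSummary", function(object) {
  covered <- sum(as.integer(names(object@sizeHistogram)) *
                 object@sizeHistogram)
  expected <- object@totalConnectedNodes + object@nSingletons
  if (length(object@sizeHistogram) && covered != expected) {
    return("size histogram does not reconcile with node counts")
  }
  TRUE
})

setMethod("show", "ComponentSummary", function(object) {
  cat("ComponentSummary:", object@nComponents, "components; largest",
      object@largestSize, "; connected nodes",
      object@totalConnectedNodes, "; singletons",
      object@nSingletons, "\n")
  if (length(object@sizeHistogram)) {
    h <- object@sizeHistogram
    cat("  sizes:", paste(sprintf("%dx%s", h, names(h)), collapse = ", "),
        "\n")
  }
})
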