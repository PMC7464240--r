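#' Threshold specification helper
#'
#' Convenience constructor for a named vector of per-metric minimum values,
#' e.g. \code{thresholdSpec(degree = 50, stress = 2e5, eigenvector = 0.05)}
#' (the whole-network replication thresholds).
#'
#' @param ... named per-metric minimum values (non-negative).
#' @return named numeric vector.
#' @export
thresholdSpec <- function(...) {
  spec <- unlist(list(...))
  if (length(spec) && (is.null(names(spec)) || any(names(spec) == ""))) {
    stop("all thresholds must be named by metric")
  }
  if (any(spec < 0)) stop("thresholds must be non-negative")
  spec
}

#' Select primary communicative genes by centrality thresholds
#'
#' Per-metric selection by inclusive comparison (value >= threshold);
#' the combined set is the union of the per-metric sets.
#'
#' @param table centrality data.frame with a \code{node} column and one
#'   column per metric.
#' @param spec named numeric vector of per-metric minimum values (see
#'   \code{\link{thresholdSpec}}).
#' @return a \linkS4class{SelectionResult}.
#' @export
selectPrimary <- function(table, spec) {
  if (!"node" %in% names(table)) stop("table must have a 'node' column")
  if (length(spec) == 0) {
    warning("empty threshold spec: nothing selected")
    return(methods::new("SelectionResult", perMetric = list(),
                        combined = character(0), thresholds = numeric(0),
                        graphSize = nrow(table)))
  }
  missing <- setdiff(names(spec), names(table))
  if (length(missing)) {
    stop("metric(s) absent from table: ", paste(missing, collapse = ", "))
  }
  perMetric <- lapply(names(spec), function(m) {
    sort(table$node[table[[m]] >= spec[[m]]])
  })
  names(perMetric) <- names(spec)
  methods::new("SelectionResult",
    perMetric = perMetric,
    combined = sort(unique(unlist(perMetric, use.names = FALSE))),
    thresholds = spec,
    graphSize = nrow(table))
}

#' Tune per-metric thresholds to exceed a target selection fraction
#'
#' Sets every metric's threshold at a common per-metric quantile q, lowering
#' q from \code{qStart} in steps of \code{qStep} until the union of the
#' per-metric selections strictly exceeds \code{targetFraction} times the
#' node count (the ">10 percent of nodes" rule).
#'
#' @param table centrality data.frame with a \code{node} column.
#' @param metrics metric column names to threshold.
#' @param targetFraction fraction of nodes the union must strictly exceed.
#' @param qStart,qStep starting quantile and step.
#' @return list with \code{thresholds} (named numeric), \code{unionSize},
#'   \code{quantile} (the q reached) and \code{selection} (the
#'   \linkS4class{SelectionResult}).
#' @export
tuneThresholds <- function(table, metrics, targetFraction = 0.10,
                           qStart = 0.99, qStep = 0.005) {
  if (nrow(table) == 0) stop("empty centrality table")
  if (!all(metrics %in% names(table))) {
    stop("metric(s) absent from table: ",
         paste(setdiff(metrics, names(table)), collapse = ", "))
  }
  if (targetFraction <= 0 || targetFraction >= 1) {
    stop("'targetFraction' must lie in (0, 1)")
  }
  target <- targetFraction * nrow(table)
  q <- qStart
  repeat {
    spec <- vapply(metrics, function(m) {
      as.numeric(stats::quantile(table[[m]], q, names = FALSE))
    }, numeric(1))
    sel <- selectPrimary(table, spec)
    if (length(combinedGenes(sel)) > target) break
    if (q <= 0) {
      stop("target fraction unreachable even with all thresholds at the ",
           "minimum")
    }
    q <- max(q - qStep, 0)
  }
  list(thresholds = spec, unionSize = length(combinedGenes(sel)),
       quantile = q, selection = sel)
}

#' Metrics with too little variance to discriminate
#'
#' A metric is flagged for exclusion when its values are all equal, or when
#' its coefficient of variation (sd/mean, requiring mean > 0) falls below
#' \code{relVarMin}.
#'
#' @param table centrality data.frame (>= 2 rows) with a \code{node} column.
#' @param relVarMin minimum coefficient of variation to keep a metric.
#' @return character vector of metric names to exclude.
#' @export
lowVarianceMetrics <- function(table, relVarMin = 0.05) {
  if (nrow(table) < 2) stop("need >= 2 rows to assess variance")
  metrics <- setdiff(names(table), "node")
  excl <- vapply(metrics, function(m) {
    v <- table[[m]]
    if (max(v) == min(v)) return(TRUE)
    mu <- mean(v)
    mu > 0 && stats::sd(v) / mu < relVarMin
  }, logical(1))
  metrics[excl]
}

#' Select top communicative genes within a module
#'
#' Same inclusive per-metric thresholding and union combination as
#' \code{\link{selectPrimary}}, applied to the centrality rows of one
#' module's members. Metrics in \code{spec} should have survived
#' \code{\link{lowVarianceMetrics}}.
#'
#' @param moduleTable centrality rows of the module's members.
#' @param spec named numeric vector of per-metric minimum values.
#' @return a \linkS4class{SelectionResult}.
#' @export
selectTopInModule <- function(moduleTable, spec) {
  selectPrimary(moduleTable, spec)
}

#' Write a selection result as TSV plus JSON provenance
#'
#' @param sel a \linkS4class{SelectionResult}.
#' @param path output TSV (node, one flag column per metric, combined);
#'   provenance goes to \code{paste0(path, ".json")}.
#' @return the path, invisibly.
#' @export
writeSelectionTSV <- function(sel, path) {
  nodes <- combinedGenes(sel)
  df <- data.frame(node = nodes)
  for (m in names(metricGenes(sel))) {
    df[[m]] <- nodes %in% metricGenes(sel)[[m]]
  }
  df$combined <- TRUE
  writeTSV(df, path)
  jsonlite::write_json(
    list(thresholds = as.list(sel@thresholds), graphSize = sel@graphSize,
         counts = as.list(selectionCounts(sel)),
         combined = length(combinedGenes(sel))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
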