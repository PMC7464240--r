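#' Build a simple undirected graph from an edge table
#'
#' @param edges data.frame whose first two columns are node identifiers;
#'   self-pairs are dropped and duplicate / reversed pairs collapsed.
#' @param nodes optional character vector of nodes to include even when
#'   isolated.
#' @return an \pkg{igraph} undirected simple graph with named vertices.
#' @export
makePPIGraph <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  vs <- sort(unique(c(lo, hi, nodes)))
  igraph::graph_from_data_frame(
    data.frame(from = lo[!dup], to = hi[!dup], stringsAsFactors = FALSE),
    directed = FALSE, vertices = vs)
}

#' Read a STRING-dialect edge list
#'
#' Expects a tab-separated file with two identifier columns
#' (\code{node1}/\code{node2} or \code{protein1}/\code{protein2}) and a
#' \code{combined_score} column. Scores on the 0--1000 integer scale are
#' detected (any score > 1) and divided by 1000. Rows with score >=
#' \code{minScore} (inclusive) are retained; self-pairs are dropped and
#' duplicate / reversed pairs collapse to one undirected edge.
#'
#' @param path TSV file path.
#' @param minScore minimum combined score on the 0--1 scale (default 0.4).
#' @return an \pkg{igraph} undirected simple graph.
#' @export
readStringEdges <- function(path, minScore = 0.4) {
  df <- readTSV(path, colClasses = "character")
  idCols <- if (all(c("node1", "node2") %in% names(df))) {
    c("node1", "node2")
  } else if (all(c("protein1", "protein2") %in% names(df))) {
    c("protein1", "protein2")
  } else {
    stop("expected identifier columns node1/node2 or protein1/protein2; ",
         "found: ", paste(names(df), collapse = ", "))
  }
  if (!"combined_score" %in% names(df)) {
    stop("expected a 'combined_score' column; found: ",
         paste(names(df), collapse = ", "))
  }
  score <- suppressWarnings(as.numeric(df$combined_score))
  if (anyNA(score)) {
    bad <- which(is.na(score))[1]
    stop("unparseable combined_score at line ", bad + 1L,
         ": '", df$combined_score[bad], "'")
  }
  if (any(score > 1)) score <- score / 1000  # 0-1000 STRING serialization
  keep <- score >= minScore
  makePPIGraph(df[keep, idCols, drop = FALSE])
}

#' Write a graph as a STRING-dialect edge TSV
#'
#' @param graph an \pkg{igraph} graph with named vertices.
#' @param path output file.
#' @param score combined score written for every edge (0--1000 scale).
#' @return the path, invisibly.
#' @export
writeEdgesTSV <- function(graph, path, score = 900L) {
  el <- igraph::as_data_frame(graph, what = "edges")
  writeTSV(data.frame(node1 = pmin(el$from, el$to),
                      node2 = pmax(el$from, el$to),
                      combined_score = rep(score, nrow(el))), path)
}

#' Write a graph as GraphML
#'
#' @param graph an \pkg{igraph} graph.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeGraphML <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Induced subgraph on a gene set
#'
#' Keeps the nodes of \code{graph} lying in \code{genes} and every edge with
#' both endpoints retained. Genes absent from the graph are ignored with a
#' message; a disjoint gene set yields an empty graph with a warning.
#'
#' @param graph an \pkg{igraph} graph with named vertices.
#' @param genes character vector of gene symbols.
#' @return the induced \pkg{igraph} subgraph.
#' @export
inducedSubgraph <- function(graph, genes) {
  present <- intersect(genes, igraph::V(graph)$name)
  nMissing <- length(setdiff(genes, present))
  if (nMissing > 0) {
    message(nMissing, " gene(s) not in graph; ignored")
  }
  if (length(present) == 0) {
    warning("no requested genes present in graph; returning empty graph")
  }
  igraph::induced_subgraph(graph, present)
}

#' Connected components, largest first
#'
#' @param graph an \pkg{igraph} graph with named vertices.
#' @return list of character vectors (each sorted), ordered by decreasing
#'   size, ties by lexicographically smallest member.
#' @export
connectedComponents <- function(graph) {
  comp <- igraph::components(graph)
  sets <- split(igraph::V(graph)$name, comp$membership)
  sets <- lapply(sets, sort)
  firsts <- vapply(sets, `[`, character(1), 1)
  unname(sets[order(-vapply(sets, length, integer(1)), firsts)])
}

#' Summarize the component structure of a graph
#'
#' "Connected nodes" are nodes in components of size >= 2; singletons are
#' counted separately.
#'
#' @param graph an \pkg{igraph} graph.
#' @return a \linkS4class{ComponentSummary}.
#' @export
summarizeComponents <- function(graph) {
  sizes <- igraph::components(graph)$csize
  if (length(sizes) == 0) {
    return(methods::new("ComponentSummary", nComponents = 0L,
                        sizeHistogram = integer(0), largestSize = 0L,
                        totalConnectedNodes = 0L, nSingletons = 0L))
  }
  h <- table(sizes)
  methods::new("ComponentSummary",
    nComponents = length(sizes),
    sizeHistogram = stats::setNames(as.integer(h), names(h)),
    largestSize = as.integer(max(sizes)),
    totalConnectedNodes = as.integer(sum(sizes[sizes >= 2])),
    nSingletons = as.integer(sum(sizes == 1)))
}

#' Read / write a paired expression study from TSV files
#'
#' \code{readExpressionTSV} rebuilds a \linkS4class{PairedExpression} from an
#' expression matrix TSV (first column \code{probe}, one column per sample),
#' a design TSV (columns \code{sample}, \code{group} with values
#' \code{patient:condition}) and a probe map TSV (\code{probe}, \code{gene}).
#'
#' @param exprPath,designPath,probeMapPath input files.
#' @return a \linkS4class{PairedExpression}.
#' @export
readExpressionTSV <- function(exprPath, designPath, probeMapPath) {
  ed <- readTSV(exprPath)
  mat <- as.matrix(ed[, -1, drop = FALSE])
  rownames(mat) <- as.character(ed[[1]])
  dd <- readTSV(designPath, colClasses = "character")
  parts <- strsplit(dd$group, ":", fixed = TRUE)
  design <- data.frame(sample = dd$sample,
                       patient = vapply(parts, `[`, character(1), 1),
                       condition = vapply(parts, `[`, character(1), 2),
                       stringsAsFactors = FALSE)
  pm <- readTSV(probeMapPath, colClasses = "character")
  PairedExpression(mat, design, pm)
}
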