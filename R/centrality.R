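#' @useDynLib commnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# CSR adjacency (0-based) for the C-level Brandes accumulation
graphToCSR <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0) return(list(ptr = 0L, adj = integer(0), n = 0L))
  el <- igraph::as_edgelist(graph, names = FALSE)
  from <- c(el[, 1], el[, 2]); to <- c(el[, 2], el[, 1])
  ord <- order(from, to)
  from <- from[ord]; to <- to[ord]
  ptr <- c(0L, cumsum(tabulate(from, nbins = n)))
  list(ptr = as.integer(ptr), adj = as.integer(to - 1L), n = n)
}

# shared Brandes pass: raw betweenness, stress, distance sums, components
brandesPass <- function(graph) {
  csr <- graphToCSR(graph)
  nodes <- igraph::V(graph)$name
  comp <- igraph::components(graph)
  compSize <- comp$csize[comp$membership]
  if (csr$n == 0) {
    return(list(nodes = character(0), betRaw = numeric(0),
                stress = numeric(0), distsum = numeric(0),
                compSize = integer(0), membership = integer(0)))
  }
  res <- .brandesAll(csr$ptr, csr$adj)
  list(nodes = nodes, betRaw = res$betweenness_raw, stress = res$stress,
       distsum = res$distsum, compSize = compSize,
       membership = comp$membership)
}

#' Degree centrality
#'
#' @param graph an \pkg{igraph} graph with named vertices.
#' @return named integer vector of incident-edge counts.
#' @export
degreeCentrality <- function(graph) {
  d <- igraph::degree(graph)
  stats::setNames(as.integer(d), igraph::V(graph)$name)
}

#' Betweenness and stress centrality
#'
#' Brandes-style accumulation over unweighted shortest paths with a parallel
#' counter for stress. For node v, stress(v) counts the distinct shortest
#' paths between unordered pairs (s,t), s != v != t, passing through v;
#' raw betweenness sums sigma_st(v)/sigma_st over the same pairs and is
#' reported normalized by (n-1)(n-2)/2 with n the size of v's connected
#' component (0 when n < 3).
#'
#' @param graph an \pkg{igraph} graph with named vertices.
#' @return data.frame with columns \code{node}, \code{betweenness} (in
#'   [0, 1]), \code{stress} (integer-valued count).
#' @export
betweennessStress <- function(graph) {
  bp <- brandesPass(graph)
  denom <- (bp$compSize - 1) * (bp$compSize - 2) / 2
  bet <- ifelse(bp$compSize >= 3, bp$betRaw / denom, 0)
  data.frame(node = bp$nodes, betweenness = bet,
             stress = round(bp$stress), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Closeness centrality (within-component convention)
#'
#' closeness(v) = (n_c - 1) / sum of geodesic distances from v to the other
#' nodes of its connected component of size n_c; isolated nodes get 0.
#'
#' @param graph an \pkg{igraph} graph with named vertices.
#' @return named numeric vector in [0, 1].
#' @export
closenessCentrality <- function(graph) {
  bp <- brandesPass(graph)
  cl <- ifelse(bp$compSize >= 2, (bp$compSize - 1) / bp$distsum, 0)
  stats::setNames(cl, bp$nodes)
}

#' Eigenvector centrality by power iteration
#'
#' Computes, per connected component, the dominant eigenvector of the
#' adjacency matrix with non-negative entries and unit Euclidean norm.
#' Iteration runs on A + I (same eigenvectors, strictly dominant leading
#' eigenvalue, so bipartite components converge); convergence is declared
#' when successive iterates differ by less than \code{tol} in max-norm.
#'
#' @param graph an \pkg{igraph} graph with named vertices.
#' @param tol convergence tolerance (max-norm of successive iterates).
#' @param maxIter iteration cap; non-convergence is an error reporting the
#'   residual.
#' @return named numeric vector, unit L2 norm per component.
#' @export
eigenvectorCentrality <- function(graph, tol = 1e-12, maxIter = 10000L) {
  nodes <- igraph::V(graph)$name
  out <- stats::setNames(numeric(length(nodes)), nodes)
  for (compNodes in connectedComponents(graph)) {
    if (length(compNodes) == 1) {
      out[compNodes] <- 1
      next
    }
    sub <- igraph::induced_subgraph(graph, compNodes)
    A <- igraph::as_adjacency_matrix(sub, sparse = TRUE)
    nm <- rownames(A)
    x <- rep(1 / sqrt(nrow(A)), nrow(A))
    converged <- FALSE
    resid <- NA_real_
    for (i in seq_len(maxIter)) {
      y <- as.numeric(A %*% x) + x   # (A + I) x
      y <- y / sqrt(sum(y^2))
      resid <- max(abs(y - x))
      x <- y
      if (resid < tol) { converged <- TRUE; break }
    }
    if (!converged) {
      stop("eigenvector power iteration did not converge after ", maxIter,
           " iterations (residual ", format(resid), "); raise maxIter")
    }
    out[nm] <- x
  }
  out
}

#' All five micro-level centrality metrics
#'
#' Degree and stress are reported raw; betweenness is normalized to [0, 1];
#' closeness uses the within-component convention; eigenvector is computed
#' per connected component with unit Euclidean norm.
#'
#' @param graph an \pkg{igraph} graph with named vertices.
#' @param tol,maxIter passed to \code{\link{eigenvectorCentrality}}.
#' @return data.frame with columns \code{node}, \code{degree},
#'   \code{stress}, \code{betweenness}, \code{closeness},
#'   \code{eigenvector}; one row per node.
#' @export
computeCentrality <- function(graph, tol = 1e-12, maxIter = 10000L) {
  bp <- brandesPass(graph)
  denom <- (bp$compSize - 1) * (bp$compSize - 2) / 2
  bet <- ifelse(bp$compSize >= 3, bp$betRaw / denom, 0)
  cl <- ifelse(bp$compSize >= 2, (bp$compSize - 1) / bp$distsum, 0)
  ev <- eigenvectorCentrality(graph, tol = tol, maxIter = maxIter)
  deg <- degreeCentrality(graph)
  data.frame(node = bp$nodes,
             degree = unname(deg[bp$nodes]),
             stress = round(bp$stress),
             betweenness = bet,
             closeness = cl,
             eigenvector = unname(ev[bp$nodes]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write / read centrality tables as TSV
#'
#' @param table data.frame from \code{\link{computeCentrality}}.
#' @param path file path.
#' @return \code{readCentralityTSV} returns the data.frame.
#' @export
writeCentralityTSV <- function(table, path) writeTSV(table, path)

#' @rdname writeCentralityTSV
#' @export
readCentralityTSV <- function(path) readTSV(path)
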