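# Independent oracles used to validate the package's native algorithms.

# random simple undirected graph with named vertices
randomTestGraph <- function(n, p, seed, prefix = "v") {
  withr::with_seed(seed, {
    nodes <- sprintf("%s%02d", prefix, seq_len(n))
    pairs <- which(upper.tri(matrix(FALSE, n, n)))
    r <- ((pairs - 1L) %% n) + 1L
    cc <- ((pairs - 1L) %/% n) + 1L
    keep <- stats::runif(length(pairs)) < p
    makePPIGraph(data.frame(a = nodes[r[keep]], b = nodes[cc[keep]]),
                 nodes = nodes)
  })
}

# exhaustive enumeration of all shortest paths between every pair, giving
# betweenness (normalized per component) and stress -- brute force, only for
# tiny graphs
bruteBetweennessStress <- function(g) {
  n <- igraph::vcount(g)
  nodes <- igraph::V(g)$name
  adj <- lapply(seq_len(n), function(i) {
    as.integer(igraph::neighbors(g, i))
  })
  comp <- igraph::components(g)
  bet <- stress <- numeric(n)
  allSimplePaths <- function(s, t) {
    paths <- list()
    visited <- rep(FALSE, n)
    rec <- function(v, path) {
      if (v == t) {
        paths[[length(paths) + 1L]] <<- path
        return(invisible())
      }
      for (w in adj[[v]]) {
        if (!visited[w]) {
          visited[w] <<- TRUE
          rec(w, c(path, w))
          visited[w] <<- FALSE
        }
      }
    }
    visited[s] <- TRUE
    rec(s, s)
    paths
  }
  if (n >= 2) {
    for (s in seq_len(n - 1)) {
      for (t in seq(s + 1, n)) {
        if (comp$membership[s] != comp$membership[t]) next
        paths <- allSimplePaths(s, t)
        lens <- vapply(paths, length, integer(1))
        sp <- paths[lens == min(lens)]
        sigma <- length(sp)
        inner <- unlist(lapply(sp, function(p) p[-c(1, length(p))]))
        if (length(inner)) {
          cnt <- table(inner)
          idx <- as.integer(names(cnt))
          stress[idx] <- stress[idx] + as.numeric(cnt)
          bet[idx] <- bet[idx] + as.numeric(cnt) / sigma
        }
      }
    }
  }
  cs <- comp$csize[comp$membership]
  betN <- ifelse(cs >= 3, bet / ((cs - 1) * (cs - 2) / 2), 0)
  data.frame(node = nodes, betweenness = betN, stress = stress,
             stringsAsFactors = FALSE)
}

# closeness oracle from igraph's distance matrix (within-component)
oracleCloseness <- function(g) {
  d <- igraph::distances(g)
  comp <- igraph::components(g)
  cs <- comp$csize[comp$membership]
  ds <- vapply(seq_len(nrow(d)), function(i) {
    sum(d[i, is.finite(d[i, ]) & seq_len(ncol(d)) != i])
  }, numeric(1))
  stats::setNames(ifelse(cs >= 2, (cs - 1) / ds, 0), rownames(d))
}

# eigenvector oracle: dense eigendecomposition per connected component
oracleEigenvector <- function(g) {
  nodes <- igraph::V(g)$name
  out <- stats::setNames(numeric(length(nodes)), nodes)
  for (compNodes in connectedComponents(g)) {
    if (length(compNodes) == 1) {
      out[compNodes] <- 1
      next
    }
    sub <- igraph::induced_subgraph(g, compNodes)
    A <- as.matrix(igraph::as_adjacency_matrix(sub))
    es <- eigen(A, symmetric = TRUE)
    v <- abs(es$vectors[, 1])
    out[rownames(A)] <- v / sqrt(sum(v^2))
  }
  out
}

# normalized mutual information between two labelings (igraph's implementation)
nmiOf <- function(a, b) igraph::compare(a, b, method = "nmi")

# truth module labels as integers aligned to a partition's nodes
truthLabels <- function(truth, nodes) {
  as.integer(factor(moduleAssignment(truth)[nodes]))
}
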