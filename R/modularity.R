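#' Newman modularity of a node partition
#'
#' Q = sum over modules c of e_c/m - gamma (d_c / 2m)^2, with m the edge
#' count, e_c the within-module edge count and d_c the summed degree of
#' module c; gamma is the resolution parameter (default 1).
#'
#' @param graph an \pkg{igraph} graph with named vertices and >= 1 edge.
#' @param assignment named vector (names = nodes) of module ids covering
#'   every node of the graph.
#' @param resolution resolution parameter gamma.
#' @return the modularity score (a real number <= 1).
#' @export
modularityScore <- function(graph, assignment, resolution = 1) {
  m <- igraph::ecount(graph)
  if (m == 0) stop("modularity is undefined on an edgeless graph")
  nodes <- igraph::V(graph)$name
  if (is.null(names(assignment)) || !all(nodes %in% names(assignment))) {
    stop("assignment must be named and cover every node")
  }
  mod <- as.integer(factor(assignment[nodes]))
  el <- igraph::as_edgelist(graph, names = TRUE)
  mi <- mod[match(el[, 1], nodes)]
  mj <- mod[match(el[, 2], nodes)]
  eWithin <- tabulate(mi[mi == mj], nbins = max(mod))
  degSum <- as.numeric(rowsum(as.numeric(igraph::degree(graph)), mod))
  sum(eWithin / m - resolution * (degSum / (2 * m))^2)
}

# one Louvain level: greedy single-node moves to the neighbouring module
# with maximal positive gain, sweeping in 'ord' until no move improves.
# Nodes 1..n; edges (ei, ej, w) without self-pairs; selfw[i] is the diagonal
# adjacency contribution A_ii of aggregated node i.
louvainOneLevel <- function(n, ei, ej, w, selfw, resolution, ord,
                            record = FALSE) {
  f <- factor(c(ei, ej), levels = seq_len(n))
  nbl <- split(c(ej, ei), f)
  nwl <- split(c(w, w), f)
  k <- selfw + vapply(nwl, sum, numeric(1))
  m2 <- sum(k)
  comm <- seq_len(n)
  Sigtot <- k
  nMoved <- 0L
  moves <- if (record) list() else NULL
  repeat {
    movedThisPass <- 0L
    for (i in ord) {
      ci <- comm[i]
      js <- nbl[[i]]; ws <- nwl[[i]]
      wByComm <- vapply(split(ws, comm[js]), sum, numeric(1))
      Sigtot[ci] <- Sigtot[ci] - k[i]
      cand <- sort(unique(c(as.integer(names(wByComm)), ci)))
      wTo <- ifelse(is.na(wByComm[as.character(cand)]), 0,
                    wByComm[as.character(cand)])
      gains <- wTo - resolution * k[i] * Sigtot[cand] / m2
      stay <- gains[cand == ci]
      best <- which.max(gains)           # first max = lowest module id
      if (cand[best] != ci && gains[best] > stay + 1e-12) {
        if (record) {
          moves[[length(moves) + 1L]] <- c(
            node = i, from = ci, to = cand[best],
            dq = unname(2 * (gains[best] - stay) / m2))
        }
        comm[i] <- cand[best]
        movedThisPass <- movedThisPass + 1L
      }
      Sigtot[comm[i]] <- Sigtot[comm[i]] + k[i]
    }
    nMoved <- nMoved + movedThisPass
    if (movedThisPass == 0L) break
  }
  list(comm = comm, nMoved = nMoved,
       moves = if (record) do.call(rbind, moves) else NULL)
}

# collapse a level onto its communities (weighted supernode graph)
aggregateLevel <- function(lev, comm) {
  nc <- max(comm)
  selfwNew <- as.numeric(rowsum(lev$selfw, comm))
  ci <- comm[lev$ei]; cj <- comm[lev$ej]
  within <- ci == cj
  if (any(within)) {
    add <- rowsum(2 * lev$w[within], ci[within])
    selfwNew[as.integer(rownames(add))] <-
      selfwNew[as.integer(rownames(add))] + as.numeric(add)
  }
  a <- pmin(ci, cj)[!within]; b <- pmax(ci, cj)[!within]
  if (length(a)) {
    key <- (a - 1) * nc + b
    agg <- rowsum(lev$w[!within], key)
    kk <- as.numeric(rownames(agg))
    eiN <- as.integer((kk - 1) %/% nc + 1)
    ejN <- as.integer((kk - 1) %% nc + 1)
    wN <- as.numeric(agg)
  } else {
    eiN <- integer(0); ejN <- integer(0); wN <- numeric(0)
  }
  list(n = nc, ei = eiN, ej = ejN, w = wN, selfw = selfwNew)
}

#' Louvain-style greedy modularity optimisation
#'
#' Two-phase heuristic: (1) repeated single-node moves to the neighbouring
#' module with maximal positive modularity gain (ties broken by the lowest
#' candidate module id) until no move improves; (2) modules are aggregated
#' into supernodes and the procedure repeats until a level produces no move.
#' The node sweep order is shuffled by \code{seed}. The returned partition's
#' modularity is never below that of the all-in-one partition.
#'
#' @param graph an \pkg{igraph} graph with named vertices and >= 1 edge.
#' @param resolution resolution parameter gamma (default 1).
#' @param seed integer seed fixing the sweep order.
#' @param recordMoves record first-level accepted moves (for diagnostics)
#'   as attribute \code{"moves"} of the result.
#' @return a \linkS4class{ModulePartition}; module ids are contiguous from
#'   0, numbered by decreasing size (ties by lexicographically smallest
#'   member).
#' @export
louvain <- function(graph, resolution = 1, seed = 0, recordMoves = FALSE) {
  if (igraph::ecount(graph) == 0) {
    stop("graph has no edges; modularity optimisation undefined")
  }
  nodes <- igraph::V(graph)$name
  n0 <- length(nodes)
  el <- igraph::as_edgelist(graph, names = FALSE)
  lev <- list(n = n0, ei = el[, 1], ej = el[, 2],
              w = rep(1, nrow(el)), selfw = numeric(n0))
  assign0 <- seq_len(n0)
  movesRec <- NULL
  level <- 0L
  repeat {
    level <- level + 1L
    ord <- withSeed(as.integer(seed) + level, sample.int(lev$n))
    res <- louvainOneLevel(lev$n, lev$ei, lev$ej, lev$w, lev$selfw,
                           resolution, ord,
                           record = (level == 1L && recordMoves))
    if (level == 1L && recordMoves) movesRec <- res$moves
    if (res$nMoved == 0L) break
    newc <- match(res$comm, sort(unique(res$comm)))
    assign0 <- newc[assign0]
    lev <- aggregateLevel(lev, newc)
    if (lev$n == 1L) break
  }

  memb <- stats::setNames(assign0, nodes)
  q <- modularityScore(graph, memb, resolution)
  qAll <- modularityScore(graph, stats::setNames(rep(1L, n0), nodes),
                          resolution)
  if (q < qAll) {        # pathological local optimum: fall back to one module
    memb <- stats::setNames(rep(1L, n0), nodes)
    q <- qAll
  }

  # renumber: size descending, ties by lexicographically smallest member
  sets <- split(nodes, memb)
  firsts <- vapply(sets, function(s) min(s), character(1))
  ord2 <- order(-vapply(sets, length, integer(1)), firsts)
  newId <- stats::setNames(seq_along(ord2) - 1L, names(sets)[ord2])
  out <- methods::new("ModulePartition",
    membership = stats::setNames(newId[as.character(memb)], nodes),
    q = q, resolution = as.numeric(resolution), seed = as.integer(seed))
  if (recordMoves) attr(out, "moves") <- movesRec
  out
}

#' Write a partition as TSV plus JSON run metadata
#'
#' @param partition a \linkS4class{ModulePartition}.
#' @param path output TSV (node, module); metadata (Q, resolution, seed)
#'   goes to \code{paste0(path, ".json")}.
#' @return the path, invisibly.
#' @export
writePartitionTSV <- function(partition, path) {
  writeTSV(data.frame(node = names(nodeModules(partition)),
                      module = unname(nodeModules(partition))), path)
  jsonlite::write_json(
    list(q = modularityQ(partition), resolution = partition@resolution,
         seed = partition@seed),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
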