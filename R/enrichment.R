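#' Intra-module top-gene subnetwork
#'
#' Induced subgraph of the primary-gene network on one module's top
#' communicative genes.
#'
#' @param graph152 the primary communicative genes' network (\pkg{igraph}).
#' @param topGenes the module's top communicative genes; must lie within
#'   \code{moduleMembers}.
#' @param moduleMembers the module's member genes.
#' @return induced \pkg{igraph} subgraph on \code{topGenes}.
#' @export
intraModuleSubnet <- function(graph152, topGenes, moduleMembers) {
  bad <- setdiff(topGenes, moduleMembers)
  if (length(bad)) {
    stop("top genes not in module: ", paste(bad, collapse = ", "))
  }
  igraph::induced_subgraph(graph152, intersect(topGenes,
                                               igraph::V(graph152)$name))
}

#' Inter-module top-gene subnetwork with edge classes
#'
#' Induced subgraph on the union of two disjoint top-gene sets; every edge
#' is labelled \code{"within-1"}, \code{"within-2"} or \code{"between"} by
#' its endpoint membership (edge attribute \code{class}).
#'
#' @param graph152 the primary communicative genes' network (\pkg{igraph}).
#' @param top1,top2 disjoint top-gene sets of the two modules.
#' @return induced \pkg{igraph} subgraph with edge attribute \code{class}.
#' @export
interModuleSubnet <- function(graph152, top1, top2) {
  overlap <- intersect(top1, top2)
  if (length(overlap)) {
    stop("top-gene sets overlap: ", paste(overlap, collapse = ", "))
  }
  sub <- igraph::induced_subgraph(
    graph152, intersect(c(top1, top2), igraph::V(graph152)$name))
  if (igraph::ecount(sub) > 0) {
    el <- igraph::as_edgelist(sub)
    in1a <- el[, 1] %in% top1
    in1b <- el[, 2] %in% top1
    cls <- ifelse(in1a & in1b, "within-1",
                  ifelse(!in1a & !in1b, "within-2", "between"))
    sub <- igraph::set_edge_attr(sub, "class", value = cls)
  }
  sub
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the study set overlaps it more than
#' expected under hypergeometric sampling from the background:
#' p = P(overlap >= observed), the upper tail of the hypergeometric
#' distribution with the set (intersected with the background) as successes
#' and the study size as draws. P-values are BH-adjusted.
#'
#' @param study character vector of study genes (must lie in
#'   \code{background}).
#' @param collection named list of gene sets (e.g. from
#'   \code{\link{readGmt}}).
#' @param background character vector of background genes; defaults in the
#'   workflow to the node set of the analyzed network.
#' @return data.frame with columns \code{set}, \code{overlap},
#'   \code{setSize}, \code{studySize}, \code{bgSize}, \code{p}, \code{fdr},
#'   sorted by p then set name.
#' @export
oraHypergeometric <- function(study, collection, background) {
  background <- unique(background)
  if (length(background) == 0) stop("background is empty")
  study <- unique(study)
  out <- setdiff(study, background)
  if (length(out)) {
    stop("study genes outside background: ", paste(out, collapse = ", "))
  }
  N <- length(background); nStudy <- length(study)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(unique(collection[[nm]]), background)
    k <- length(intersect(study, set))
    p <- stats::phyper(k - 1, length(set), N - length(set), nStudy,
                       lower.tail = FALSE)
    data.frame(set = nm, overlap = k, setSize = length(set),
               studySize = nStudy, bgSize = N, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- bhAdjust(res$p)
  res <- res[order(res$p, res$set), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read / write GMT gene-set files
#'
#' Tab-separated gene-set format: set name, description, then member gene
#' symbols.
#'
#' @param path GMT file path.
#' @return \code{readGmt} returns a named list of character vectors.
#' @export
readGmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname readGmt
#' @param collection named list of gene sets.
#' @export
writeGmt <- function(collection, path) {
  fgsea::writeGmtPathways(collection, path)
  invisible(path)
}
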