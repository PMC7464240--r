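writeEdgeFixture <- function(df, path = withr::local_tempfile(
                               fileext = ".tsv",
                               .local_envir = parent.frame())) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("STRING edge reading dedupes, drops self-pairs and thresholds", {
  p <- writeEdgeFixture(data.frame(
    node1 = c("A", "B", "A", "C"),
    node2 = c("B", "A", "A", "D"),
    combined_score = c(900, 900, 700, 150)))
  g <- readStringEdges(p, minScore = 0.4)
  expect_setequal(igraph::V(g)$name, c("A", "B"))
  expect_equal(igraph::ecount(g), 1)

  # inclusive boundary: 400 on the 0-1000 scale is exactly 0.4
  p2 <- writeEdgeFixture(data.frame(node1 = "A", node2 = "B",
                                    combined_score = 400))
  expect_equal(igraph::ecount(readStringEdges(p2, minScore = 0.4)), 1)

  # scores already on [0,1] are not rescaled
  p3 <- writeEdgeFixture(data.frame(node1 = c("A", "C"),
                                    node2 = c("B", "D"),
                                    combined_score = c(0.9, 0.2)))
  g3 <- readStringEdges(p3, minScore = 0.4)
  expect_setequal(igraph::V(g3)$name, c("A", "B"))

  # protein1/protein2 dialect accepted
  p4 <- writeEdgeFixture(data.frame(protein1 = "A", protein2 = "B",
                                    combined_score = 500))
  expect_equal(igraph::ecount(readStringEdges(p4)), 1)
})

test_that("malformed edge files raise informative errors", {
  p <- writeEdgeFixture(data.frame(node1 = "A", node2 = "B", score = 1))
  expect_error(readStringEdges(p), "combined_score")
  p2 <- writeEdgeFixture(data.frame(node1 = c("A", "B"),
                                    node2 = c("B", "C"),
                                    combined_score = c("900", "high")))
  expect_error(readStringEdges(p2), "line 3")
  p3 <- writeEdgeFixture(data.frame(a = "A", b = "B", combined_score = 1))
  expect_error(readStringEdges(p3), "node1")
})

test_that("induced subgraphs restrict nodes and edges correctly", {
  tri <- makePPIGraph(data.frame(a = c("A", "B", "C"),
                                 b = c("B", "C", "A")))
  sub <- inducedSubgraph(tri, c("A", "B"))
  expect_setequal(igraph::V(sub)$name, c("A", "B"))
  expect_equal(igraph::ecount(sub), 1)

  same <- inducedSubgraph(tri, c("A", "B", "C"))
  expect_equal(igraph::ecount(same), 3)

  expect_warning(empty <- inducedSubgraph(tri, c("X", "Y")), "no requested")
  expect_equal(igraph::vcount(empty), 0)

  # property: induced edges are always a subset of the parent's
  for (s in 1:10) {
    g <- randomTestGraph(12, 0.3, seed = s)
    pick <- igraph::V(g)$name[1:6]
    sub <- suppressMessages(inducedSubgraph(g, pick))
    canon <- function(gr) {
      el <- igraph::as_edgelist(gr)
      paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    }
    expect_true(all(canon(sub) %in% canon(g)))
  }
})

test_that("components are ordered by size then lexicographic member", {
  g <- makePPIGraph(data.frame(a = c("A", "C"), b = c("B", "D")),
                    nodes = c("A", "B", "C", "D", "E"))
  comps <- connectedComponents(g)
  expect_equal(comps, list(c("A", "B"), c("C", "D"), "E"))

  conn <- makePPIGraph(data.frame(a = c("A", "B"), b = c("B", "C")))
  expect_length(connectedComponents(conn), 1)

  pp <- generatePPI(moduleSizes = c(10, 8), nBackground = 0, pIn = 1,
                    pOut = 0, nHubs = 0, hubExtraDegree = 0,
                    nSmallComponents = 3, seed = 2)
  expect_length(connectedComponents(pp$graph), 2 + 3)
})

test_that("component summaries reconcile node counts", {
  empty <- makePPIGraph(data.frame(a = character(0), b = character(0)))
  s0 <- summarizeComponents(empty)
  expect_equal(s0@nComponents, 0L)
  expect_equal(s0@totalConnectedNodes, 0L)

  one <- makePPIGraph(data.frame(a = "A", b = "B"))
  s1 <- summarizeComponents(one)
  expect_equal(s1@nComponents, 1L)
  expect_equal(s1@totalConnectedNodes, 2L)

  g <- makePPIGraph(data.frame(a = c("A", "C", "D"), b = c("B", "D", "E")),
                    nodes = LETTERS[1:7])
  s <- summarizeComponents(g)
  expect_equal(s@nComponents, 4L)        # {A,B}, {C,D,E}, {F}, {G}
  expect_equal(s@largestSize, 3L)
  expect_equal(s@totalConnectedNodes, 5L)
  expect_equal(s@nSingletons, 2L)
  covered <- sum(as.integer(names(s@sizeHistogram)) * s@sizeHistogram)
  expect_equal(covered, igraph::vcount(g))
})

test_that("edge lists survive a write/read round trip", {
  for (s in 1:5) {
    g <- randomTestGraph(15, 0.25, seed = s)
    g <- igraph::delete_vertices(g, igraph::degree(g) == 0)
    p <- withr::local_tempfile(fileext = ".tsv")
    writeEdgesTSV(g, p)
    g2 <- readStringEdges(p, minScore = 0)
    expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
    canon <- function(gr) {
      el <- igraph::as_edgelist(gr)
      sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
    }
    expect_identical(canon(g2), canon(g))
  }
})

test_that("expression TSV round trip preserves the study", {
  ex <- generateExpression(nGenes = 40, nPairs = 4, seed = 6)
  d <- withr::local_tempdir()
  mat <- SummarizedExperiment::assay(ex$expression)
  utils::write.table(data.frame(probe = rownames(mat), mat,
                                check.names = FALSE),
                     file.path(d, "e.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  des <- pairedDesign(ex$expression)
  utils::write.table(data.frame(sample = des$sample,
                                group = paste0(des$patient, ":",
                                               des$condition)),
                     file.path(d, "d.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pm <- probeMap(ex$expression)
  utils::write.table(data.frame(probe = names(pm), gene = unname(pm)),
                     file.path(d, "m.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  back <- readExpressionTSV(file.path(d, "e.tsv"), file.path(d, "d.tsv"),
                            file.path(d, "m.tsv"))
  expect_equal(SummarizedExperiment::assay(back),
               SummarizedExperiment::assay(ex$expression),
               tolerance = 1e-10)
  expect_identical(probeMap(back), pm)
  expect_identical(pairedDesign(back), des)
})
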