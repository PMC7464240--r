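test_that("expression generation is reproducible and respects the null", {
  a <- generateExpression(nGenes = 50, nPairs = 5, seed = 3)
  b <- generateExpression(nGenes = 50, nPairs = 5, seed = 3)
  expect_identical(SummarizedExperiment::assay(a$expression),
                   SummarizedExperiment::assay(b$expression))
  expect_identical(effectSizes(a$truth), effectSizes(b$truth))
  c <- generateExpression(nGenes = 50, nPairs = 5, seed = 4)
  expect_false(identical(SummarizedExperiment::assay(a$expression),
                         SummarizedExperiment::assay(c$expression)))

  # null construction: no differential genes, paired differences centred on 0
  nul <- generateExpression(nGenes = 400, nPairs = 40, deFraction = 0,
                            noiseSd = 0.5, probesPerGene = 1, seed = 9)
  expect_length(deGenes(nul$truth), 0)
  expect_true(all(effectSizes(nul$truth) == 0))
  mat <- SummarizedExperiment::assay(nul$expression)
  des <- pairedDesign(nul$expression)
  pats <- unique(des$patient)
  d <- mat[, paste0(pats, "_LL")] - mat[, paste0(pats, "_NL")]
  # grand mean of per-gene logFC is ~ N(0, noiseSd*sqrt(2/(n*G)))
  se <- 0.5 * sqrt(2 / length(d))
  expect_lt(abs(mean(d)), 5 * se)
})

test_that("expression generator validates inputs and wires multi-probe genes", {
  expect_error(generateExpression(nGenes = 0, nPairs = 5, seed = 1),
               "nGenes")
  expect_error(generateExpression(nGenes = 10, nPairs = 1, seed = 1),
               "nPairs")
  expect_error(generateExpression(nGenes = 10, nPairs = 5, deFraction = 2,
                                  seed = 1), "deFraction")
  expect_error(generateExpression(nGenes = 10, nPairs = 5, noiseSd = 0,
                                  seed = 1), "noiseSd")

  ex <- generateExpression(nGenes = 30, nPairs = 4, seed = 2)
  pm <- probeMap(ex$expression)
  expect_gt(max(table(pm)), 1)  # at least one gene with >= 2 probes
  expect_true(all(is.finite(SummarizedExperiment::assay(ex$expression))))
})

test_that("planted-partition graphs have the constructed component profile", {
  expect_error(generatePPI(pIn = 0.1, pOut = 0.2, seed = 1), "pIn")

  pp <- generatePPI(moduleSizes = c(20, 15), nBackground = 0, pIn = 0.4,
                    pOut = 0, nHubs = 0, hubExtraDegree = 0,
                    nSmallComponents = 4, seed = 1)
  comp <- igraph::components(pp$graph)
  # isolated module nodes (possible at pIn < 1) only add components
  nIsolated <- sum(comp$csize == 1)
  expect_equal(comp$no - nIsolated, 2 + 4)
  expect_true(igraph::is_simple(pp$graph))
  expect_setequal(unique(moduleAssignment(pp$truth)),
                  c("module1", "module2", "background"))
})

test_that("within-module edge counts follow the binomial expectation", {
  s <- 30; pIn <- 0.3
  nExp <- pIn * s * (s - 1) / 2
  tot <- 0
  nSeeds <- 20
  for (i in seq_len(nSeeds)) {
    pp <- generatePPI(moduleSizes = c(s, 10), nBackground = 0, pIn = pIn,
                      pOut = 0, nHubs = 0, hubExtraDegree = 0,
                      nSmallComponents = 0, seed = i)
    m1 <- names(moduleAssignment(pp$truth))[
      moduleAssignment(pp$truth) == "module1"]
    tot <- tot + igraph::ecount(igraph::induced_subgraph(pp$graph, m1))
  }
  sdTot <- sqrt(nSeeds * nExp * (1 - pIn))
  expect_lt(abs(tot - nSeeds * nExp), 4 * sdTot)
})

test_that("planted hubs dominate the degree ranking", {
  # hubExtraDegree (50) is >= 5x the mean background degree at the defaults
  hits <- vapply(1:10, function(s) {
    pp <- generatePPI(seed = s)
    d <- igraph::degree(pp$graph)
    top <- names(sort(d, decreasing = TRUE))[seq_along(hubGenes(pp$truth))]
    mean(hubGenes(pp$truth) %in% top)
  }, numeric(1))
  expect_gte(mean(hits), 0.95)
})

test_that("fixture bundles round-trip and are byte-stable", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  args <- list(nGenes = 120, nPairs = 6, ppiArgs = list(
    moduleSizes = c(12, 8), nBackground = 40, pIn = 0.4, pOut = 0.02,
    nHubs = 2, hubExtraDegree = 10, nSmallComponents = 3))
  m1 <- do.call(writeFixtureBundle, c(list(d1, seed = 5), args))
  m2 <- do.call(writeFixtureBundle, c(list(d2, seed = 5), args))
  for (f in m1$file) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }

  study <- attr(m1, "study")
  expect_equal(m1$rows[m1$file == "expression.tsv"],
               nrow(study$expression))
  expect_equal(m1$rows[m1$file == "edges.tsv"],
               igraph::ecount(study$graph))
  expect_equal(m1$rows[m1$file == "truth.tsv"],
               length(effectSizes(study$truth)))

  back <- readFixtureBundle(d1)
  expect_setequal(igraph::V(back$graph)$name,
                  igraph::V(study$graph)$name)
  elA <- igraph::as_edgelist(back$graph)
  elB <- igraph::as_edgelist(study$graph)
  canon <- function(el) sort(paste(pmin(el[, 1], el[, 2]),
                                   pmax(el[, 1], el[, 2])))
  expect_identical(canon(elA), canon(elB))
  expect_equal(effectSizes(back$truth), effectSizes(study$truth),
               tolerance = 1e-6)
  expect_identical(moduleAssignment(back$truth),
                   moduleAssignment(study$truth))
  expect_setequal(hubGenes(back$truth), hubGenes(study$truth))
  expect_equal(
    unname(SummarizedExperiment::assay(back$expression)),
    unname(signif(SummarizedExperiment::assay(study$expression), 7)),
    tolerance = 1e-6)
})

test_that("a coherent study marks every network gene differential", {
  st <- generateStudy(nGenes = 250, nPairs = 6,
                      ppiArgs = list(moduleSizes = c(15, 10),
                                     nBackground = 60, pIn = 0.4,
                                     pOut = 0.02, nHubs = 2,
                                     hubExtraDegree = 10,
                                     nSmallComponents = 2), seed = 8)
  netGenes <- igraph::V(st$graph)$name
  expect_true(all(netGenes %in% deGenes(st$truth)))
  expect_true(all(abs(effectSizes(st$truth)[netGenes]) >= 1))
  expect_true(all(netGenes %in% probeMap(st$expression)))
})
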