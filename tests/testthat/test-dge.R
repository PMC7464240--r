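# helper: PairedExpression straight from a matrix of paired differences is
# awkward; build one from NL = 0 baseline and LL = difference instead
exprFromDiffs <- function(d) {
  n <- ncol(d)
  probes <- rownames(d)
  patients <- sprintf("P%02d", seq_len(n))
  nl <- matrix(5, nrow(d), n)  # constant NL baseline
  ll <- nl + d
  mat <- cbind(nl, ll)
  colnames(mat) <- c(paste0(patients, "_NL"), paste0(patients, "_LL"))
  rownames(mat) <- probes
  design <- data.frame(sample = colnames(mat),
                       patient = rep(patients, 2),
                       condition = rep(c("NL", "LL"), each = n))
  PairedExpression(mat, design,
                   data.frame(probe = probes, gene = probes))
}

test_that("equal per-probe variances reproduce the classical paired t", {
  set.seed(1)
  n <- 8
  base <- scale(rnorm(n), scale = FALSE)[, 1]  # centred, fixed
  d <- t(vapply(1:40, function(i) i / 10 + base, numeric(n)))
  rownames(d) <- sprintf("p%02d", 1:40)
  expr <- exprFromDiffs(d)
  tab <- moderatedPairedT(expr)
  classical <- apply(d, 1, function(x) mean(x) / (sd(x) / sqrt(n)))
  expect_equal(tab$t_mod, unname(classical), tolerance = 1e-12)
  expect_true(is.infinite(attr(tab, "priorDf")))
})

test_that("forcing zero prior df gives exactly the classical paired t", {
  set.seed(11)
  d <- matrix(rnorm(50 * 6), 50, 6,
              dimnames = list(sprintf("p%02d", 1:50), NULL))
  expr <- exprFromDiffs(d)
  tab <- moderatedPairedT(expr, priorDf = 0)
  cl <- apply(d, 1, function(x) mean(x) / (sd(x) / sqrt(6)))
  pcl <- 2 * pt(abs(cl), df = 5, lower.tail = FALSE)
  expect_equal(tab$t_mod, unname(cl), tolerance = 1e-12)
  expect_equal(tab$p, unname(pcl), tolerance = 1e-12)
})

test_that("a zero-variance probe gets a finite, large moderated t", {
  set.seed(2)
  d <- rbind(const = rep(1, 4),
             matrix(rnorm(30 * 4, sd = 0.7), 30, 4))
  rownames(d)[-1] <- sprintf("p%02d", 1:30)
  expr <- exprFromDiffs(d)
  tab <- moderatedPairedT(expr)
  row <- tab[tab$probe == "const", ]
  expect_equal(row$logFC, 1)
  expect_true(is.finite(row$t_mod))
  expect_gt(row$t_mod, max(abs(tab$t_mod[tab$probe != "const"])))
  expect_gt(attr(tab, "priorDf"), 0)
})

test_that("all-zero variance is rejected and unpaired designs are named", {
  d <- matrix(1, 5, 4, dimnames = list(letters[1:5], NULL))
  expr <- exprFromDiffs(d)
  expect_error(moderatedPairedT(expr), "zero variance")

  mat <- matrix(rnorm(8), 2, 4,
                dimnames = list(c("p1", "p2"),
                                c("s1", "s2", "s3", "s4")))
  badDesign <- data.frame(sample = colnames(mat),
                          patient = c("P1", "P1", "P2", "P3"),
                          condition = c("NL", "LL", "NL", "LL"))
  expect_error(PairedExpression(mat, badDesign,
                                c(p1 = "g1", p2 = "g2")),
               "P2")
})

test_that("moderated t agrees with the limma oracle on regular data", {
  skip_if_not_installed("limma")
  ex <- generateExpression(nGenes = 300, nPairs = 12, deFraction = 0.2,
                           seed = 7)
  tab <- moderatedPairedT(ex$expression)
  des <- pairedDesign(ex$expression)
  mat <- SummarizedExperiment::assay(ex$expression)
  pats <- unique(des$patient)
  d <- mat[, paste0(pats, "_LL")] - mat[, paste0(pats, "_NL")]
  fit <- limma::eBayes(limma::lmFit(d, matrix(1, ncol(d), 1)))
  expect_equal(tab$logFC, unname(fit$coefficients[, 1]), tolerance = 1e-10)
  expect_equal(tab$t_mod, unname(fit$t[, 1]), tolerance = 1e-9)
  expect_equal(tab$p, unname(fit$p.value[, 1]), tolerance = 1e-9)
  expect_equal(attr(tab, "priorDf"), fit$df.prior, tolerance = 1e-8)
})

test_that("BH adjustment matches the hand-computed step-up rule", {
  # min over j >= i of m p(j) / j, computed by hand for the fixture
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.37), 0.37)
  expect_equal(bhAdjust(rep(0.2, 7)), rep(0.2, 7))
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bhAdjust(c(0.1, -0.1)), "\\[0, 1\\]")

  set.seed(5)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bhAdjust(p)[perm], bhAdjust(p[perm]))
})

test_that("DEG selection applies strict p/fdr and inclusive logFC cutoffs", {
  tab <- data.frame(
    gene = c("a", "b", "c", "d"),
    logFC = c(0.9, -1.0, 2.0, 1.5),
    p = c(1e-6, 0.005, 0.02, 0.001),
    fdr = c(1e-5, 0.009, 0.03, 0.002))
  sel <- selectDEGs(tab)
  expect_setequal(sel$gene, c("b", "d"))  # a: |logFC| < 1; c: p/fdr too big

  # truncation to topN by ascending fdr
  big <- data.frame(gene = sprintf("g%04d", 1:3000),
                    logFC = rep(2, 3000),
                    p = rep(1e-6, 3000),
                    fdr = seq(1e-8, 1e-3, length.out = 3000))
  out <- selectDEGs(big, topN = 2000)
  expect_equal(nrow(out), 2000)
  expect_equal(out$gene, big$gene[1:2000])
})

test_that("probe collapse keeps the signed max-|logFC| probe", {
  tab <- data.frame(
    probe = c("x1", "x2", "y1", "z1", "z2"),
    logFC = c(1.2, -2.5, 0.5, 1.0, -1.0),
    t_mod = 1:5, p = seq(0.01, 0.05, by = 0.01),
    fdr = seq(0.02, 0.1, by = 0.02))
  map <- c(x1 = "X", x2 = "X", y1 = "Y", z1 = "Z", z2 = "Z")
  out <- collapseProbes(tab, map)
  expect_equal(out$logFC[out$gene == "X"], -2.5)    # sign preserved
  expect_equal(out$p[out$gene == "X"], 0.02)        # carried from x2
  expect_equal(out$logFC[out$gene == "Y"], 0.5)     # single probe unchanged
  expect_equal(out$logFC[out$gene == "Z"], 1.0)     # tie -> smallest probe id

  expect_error(collapseProbes(tab, map[-1]), "x1")

  # idempotent on gene-keyed tables (identity map)
  idMap <- stats::setNames(out$gene, out$gene)
  again <- collapseProbes(out, idMap)
  expect_equal(again, out)
})

test_that("estimated logFC tracks the true effects", {
  ex <- generateExpression(nGenes = 500, nPairs = 30, deFraction = 0.3,
                           effectRange = c(2, 2), noiseSd = 0.5, seed = 5)
  tab <- collapseProbes(moderatedPairedT(ex$expression),
                        probeMap(ex$expression))
  r <- cor(tab$logFC, effectSizes(ex$truth)[tab$gene])
  expect_gte(r, 0.95)
})
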