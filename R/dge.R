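#' Empirical-Bayes moderated paired t-test
#'
#' For each probe, computes the paired differences d_i = LL_i - NL_i across
#' patients, the mean difference (logFC) and its sample variance, then shrinks
#' the per-probe variances toward a common prior estimated by the method of
#' moments on log sample variances (Smyth-style): with prior degrees of
#' freedom d0 and prior variance s0^2, the posterior variance is
#' (d0 s0^2 + d s^2) / (d0 + d) and the moderated t is
#' logFC / (s_post / sqrt(n)), referred to a t distribution on d0 + d degrees
#' of freedom (capped at the pooled residual df).
#'
#' When the moment estimator yields infinite d0 (no excess variability of the
#' log variances), shrinkage is complete: every posterior variance equals the
#' common prior, taken as the mean sample variance, and p-values use the
#' normal limit. Probes with zero sample variance enter the hyperparameter
#' estimation offset to 1e-5 times the median variance, but their posterior
#' variance is the usual shrunk combination, so their moderated t is finite
#' whenever d0 > 0.
#'
#' @param expr a \linkS4class{PairedExpression}.
#' @param priorDf optional forced prior degrees of freedom; \code{priorDf=0}
#'   reproduces the classical paired t exactly.
#' @return data.frame keyed by \code{probe} with columns \code{logFC},
#'   \code{t_mod}, \code{p}, \code{fdr}, \code{df_total}; hyperparameters are
#'   attached as attributes \code{priorDf} and \code{priorVar}.
#' @export
moderatedPairedT <- function(expr, priorDf = NULL) {
  stopifnot(methods::is(expr, "PairedExpression"))
  methods::validObject(expr)
  des <- pairedDesign(expr)
  mat <- SummarizedExperiment::assay(expr)
  patients <- unique(des$patient)
  n <- length(patients)
  if (n < 2) stop("need >= 2 patient pairs")
  llCols <- des$sample[match(paste0(patients, ".LL"),
                             paste0(des$patient, ".", des$condition))]
  nlCols <- des$sample[match(paste0(patients, ".NL"),
                             paste0(des$patient, ".", des$condition))]
  d <- mat[, llCols, drop = FALSE] - mat[, nlCols, drop = FALSE]

  logFC <- rowMeans(d)
  s2 <- rowSums((d - logFC)^2) / (n - 1)
  df <- n - 1

  if (all(s2 == 0)) {
    stop("all probes have zero variance of paired differences; ",
         "hyperparameters cannot be estimated")
  }

  if (is.null(priorDf)) {
    hp <- fitVarPrior(s2, df)
  } else {
    hp <- list(df0 = priorDf,
               s20 = if (is.finite(priorDf) && priorDf > 0)
                 mean(s2) else mean(s2))
  }
  d0 <- hp$df0; s20 <- hp$s20
  if (is.finite(d0)) {
    s2post <- (d0 * s20 + df * s2) / (d0 + df)
  } else {
    s2post <- rep(s20, length(s2))  # complete shrinkage
  }
  tmod <- logFC / sqrt(s2post / n)
  dfTotal <- min(d0 + df, length(s2) * df)
  p <- 2 * stats::pt(abs(tmod), df = dfTotal, lower.tail = FALSE)

  out <- data.frame(probe = rownames(mat), logFC = logFC, t_mod = tmod,
                    p = p, fdr = bhAdjust(p),
                    df_total = rep(dfTotal, length(s2)),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "priorDf") <- d0
  attr(out, "priorVar") <- s20
  out
}

# method-of-moments fit of the scaled inverse chi-square variance prior on
# log sample variances; zero variances are offset for estimation only
fitVarPrior <- function(s2, df) {
  x <- pmax(s2, 0)
  m <- stats::median(x)
  if (m == 0) stop("more than half of the variances are zero")
  x <- pmax(x, 1e-5 * m)
  e <- log(x) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1) - trigamma(df / 2)
  if (evar > 0) {
    df0 <- 2 * trigammaInv(evar)
    s20 <- exp(emean + digamma(df0 / 2) - log(df0 / 2))
  } else {
    df0 <- Inf
    s20 <- mean(x)
  }
  list(df0 = df0, s20 = s20)
}

# inverse of the trigamma function by Newton iteration on 1/trigamma
trigammaInv <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: adjusted p(i) = min over j >= i of m p(j) / j for
#' p sorted ascending, clipped at 1, returned in input order.
#'
#' @param p vector of p-values in [0, 1].
#' @return vector of BH-adjusted values, same length and order.
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Select differentially expressed rows
#'
#' Applies the cutoff rule p < pMax AND fdr < fdrMax AND |logFC| >=
#' minAbsLogfc (p and fdr strict, logFC inclusive), then truncates to the
#' top \code{topN} rows ranked by ascending fdr, ties broken by descending
#' |logFC|, then lexicographic row key.
#'
#' @param table a data.frame with columns \code{logFC}, \code{p}, \code{fdr}
#'   and a key column \code{probe} or \code{gene}.
#' @param pMax,fdrMax strict upper bounds on p and fdr.
#' @param minAbsLogfc inclusive lower bound on |logFC|.
#' @param topN maximum number of rows returned.
#' @return the selected subset, ranked.
#' @export
selectDEGs <- function(table, pMax = 0.01, fdrMax = 0.01, minAbsLogfc = 1,
                       topN = 2000) {
  key <- intersect(c("probe", "gene"), names(table))[1]
  if (is.na(key)) stop("table must have a 'probe' or 'gene' key column")
  need <- c("logFC", "p", "fdr")
  if (!all(need %in% names(table))) {
    stop("table must have columns: ", paste(need, collapse = ", "))
  }
  keep <- table$p < pMax & table$fdr < fdrMax &
    abs(table$logFC) >= minAbsLogfc
  sel <- table[keep, , drop = FALSE]
  ord <- order(sel$fdr, -abs(sel$logFC), sel[[key]])
  utils::head(sel[ord, , drop = FALSE], topN)
}

#' Collapse probe-level statistics to gene level
#'
#' For each gene the retained row is the probe whose |logFC| is maximal
#' (sign preserved; that probe's t, p, fdr carried along). Ties are broken by
#' the lexicographically smallest probe ID.
#'
#' @param table probe-keyed data.frame (column \code{probe}; a gene-keyed
#'   table may be passed with an identity map, making the operation
#'   idempotent).
#' @param probeMap data.frame (probe, gene) or named character vector.
#' @return gene-keyed data.frame, one row per gene, sorted by gene.
#' @export
collapseProbes <- function(table, probeMap) {
  key <- intersect(c("probe", "gene"), names(table))[1]
  if (is.na(key)) stop("table must have a 'probe' or 'gene' key column")
  map <- asProbeMap(probeMap)
  ids <- as.character(table[[key]])
  unmapped <- setdiff(ids, names(map))
  if (length(unmapped)) {
    stop("probes not in probeMap: ", paste(unmapped, collapse = ", "))
  }
  gene <- unname(map[ids])
  ord <- order(gene, -abs(table$logFC), ids)
  t2 <- table[ord, , drop = FALSE]
  first <- !duplicated(gene[ord])
  out <- t2[first, , drop = FALSE]
  out$gene <- gene[ord][first]
  out <- out[, c("gene", setdiff(names(out), c("gene", "probe"))),
             drop = FALSE]
  rownames(out) <- NULL
  out[order(out$gene), , drop = FALSE]
}

#' Write / read DGE tables as TSV
#'
#' @param table a DGE data.frame.
#' @param path file path.
#' @return \code{readDGETSV} returns the data.frame.
#' @export
writeDGETSV <- function(table, path) writeTSV(table, path)

#' @rdname writeDGETSV
#' @export
readDGETSV <- function(path) readTSV(path)
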