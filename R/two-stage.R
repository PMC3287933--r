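#' Names of the five testing-stage methods
#'
#' Two logistic-regression score tests (raw common genotypes, or the
#' common-variant summary score, each augmented by the combined rare-variant
#' weighted sum) and three kernel machine tests (linear kernel with
#' WS_combined, linear kernel with WS_nonsyn, quadratic kernel with
#' WS_combined; the gene-environment kernel is always linear).
#'
#' @export
testingMethods <- c("logistic_regression", "logistic_common_score",
                    "linear_rare_ws_combined", "linear_rare_ws_nonsyn",
                    "quadratic_rare_ws_combined")

#' Subpopulation labels for screening
#'
#' Uses the sample table's `subpopulation` column when present; otherwise
#' assigns labels by k-means with 3 centers on the two population-structure
#' PCs (which must have been computed), mirroring the three continental
#' clusters the PCs are expected to separate.
#'
#' @param x a `SnpSetExperiment`.
#' @return character vector of labels, one per sample.
#' @export
subpopLabels <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("subpopulation" %in% colnames(cd) && !anyNA(cd$subpopulation))
    return(as.character(cd$subpopulation))
  if (!all(c("pc1", "pc2") %in% colnames(cd)))
    stop("no subpopulation labels and no PCs; run computePopulationPCs() first")
  km <- stats::kmeans(cbind(cd$pc1, cd$pc2), centers = 3, nstart = 10)
  paste0("cluster", km$cluster)
}

#' Screen one gene by permutation tests
#'
#' Runs the screening-stage battery for a single SNP set: (a) Hotelling
#' T-squared on the gene's common-variant genotype vectors, affected versus
#' unaffected, separately within each subpopulation; (b) a two-dimensional
#' Hotelling T-squared on `(WS_syn, WS_nonsyn)` over the whole population;
#' (c) Fisher-z gene-environment correlation tests using the common summary
#' score and `WS_nonsyn`. All p-values come from permuting disease status
#' (totals preserved); everything that depends on status -- Madsen-Browning
#' weights, summary-score coefficients, group membership -- is recomputed on
#' each permutation. Tests that do not apply (no common variants, no rare
#' variants, degenerate observed statistic) are recorded as `NA`
#' (unavailable), never as p = 1. The gene passes when any available p-value
#' is below `threshold`.
#'
#' @param x `SnpSetExperiment` with `status`, `environment` sample columns,
#'   `frequency_class` variant metadata, and subpopulation labels or PCs.
#' @param gene gene symbol.
#' @param threshold screening p-value cutoff (default 0.1).
#' @param B permutations per test (default 1000).
#' @param seed optional integer seed.
#' @return list with elements `gene`, `pCommon` (named by subpopulation),
#'   `pRare2d`, `pGeCommon`, `pGeRare`, `passed`.
#' @export
screenGene <- function(x, gene, threshold = 0.1, B = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  si <- sampleInfo(x)
  status <- si$status
  env <- si$environment
  sub <- geneSubset(x, gene)
  rd <- SummarizedExperiment::rowData(sub)
  g <- genoMatrix(sub)
  commonIds <- rownames(sub)[rd$frequency_class == "common"]
  synIds <- rownames(sub)[rd$frequency_class == "rare" &
                          rd$functional_class == "synonymous"]
  nonsynIds <- rownames(sub)[rd$frequency_class == "rare" &
                             rd$functional_class == "nonsynonymous"]
  gC <- g[, commonIds, drop = FALSE]
  gCimp <- if (length(commonIds)) meanImpute(gC) else NULL
  gSyn <- g[, synIds, drop = FALSE]
  gNon <- g[, nonsynIds, drop = FALSE]
  gSynImp <- if (length(synIds)) meanImpute(gSyn) else NULL
  gNonImp <- if (length(nonsynIds)) meanImpute(gNon) else NULL
  n <- nrow(g)

  permP <- function(statFn, st) {
    tryCatch(pValue(permutationPvalue(statFn, st, B = B)),
             error = function(e) NA_real_)
  }

  wsClass <- function(raw, imp, st) {
    if (is.null(imp)) return(numeric(n))
    drop(imp %*% (1 / madsenBrowningWeights(raw, st)))
  }

  # (a) common variants within each subpopulation
  pops <- subpopLabels(x)
  pCommon <- stats::setNames(rep(NA_real_, length(unique(pops))),
                             sort(unique(pops)))
  if (length(commonIds)) {
    for (pop in names(pCommon)) {
      idx <- which(pops == pop)
      gPop <- gCimp[idx, , drop = FALSE]
      statFn <- function(st)
        .hotellingStat(gPop[st == 1, , drop = FALSE],
                       gPop[st == 0, , drop = FALSE])
      pCommon[pop] <- permP(statFn, status[idx])
    }
  }

  # (b) 2D Hotelling on the class-specific weighted sums, whole population
  pRare2d <- NA_real_
  if (length(synIds) || length(nonsynIds)) {
    statFn <- function(st) {
      ws <- cbind(wsClass(gSyn, gSynImp, st), wsClass(gNon, gNonImp, st))
      .hotellingStat(ws[st == 1, , drop = FALSE],
                     ws[st == 0, , drop = FALSE])
    }
    pRare2d <- permP(statFn, status)
  }

  # (c) gene-environment correlation tests
  pGeCommon <- NA_real_
  if (length(commonIds)) {
    statFn <- function(st) {
      sc <- drop(gCimp %*% freqContrastCoeffs(gC, st))
      abs(.geZStat(sc, env, st))
    }
    pGeCommon <- permP(statFn, status)
  }
  pGeRare <- NA_real_
  if (length(nonsynIds)) {
    statFn <- function(st)
      abs(.geZStat(wsClass(gNon, gNonImp, st), env, st))
    pGeRare <- permP(statFn, status)
  }

  ps <- c(pCommon, rare2d = pRare2d, geCommon = pGeCommon, geRare = pGeRare)
  list(gene = gene, pCommon = pCommon, pRare2d = pRare2d,
       pGeCommon = pGeCommon, pGeRare = pGeRare,
       passed = any(ps < threshold, na.rm = TRUE))
}

#' Flatten screening reports into a data.frame
#'
#' @param reports list of [screenGene()] results.
#' @return data.frame, one row per gene.
#' @export
screenReportTable <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    out <- data.frame(gene = r$gene, stringsAsFactors = FALSE)
    for (pop in names(r$pCommon)) out[[paste0("p_common_", pop)]] <- r$pCommon[[pop]]
    out$p_rare_2d <- r$pRare2d
    out$p_ge_common <- r$pGeCommon
    out$p_ge_rare <- r$pGeRare
    out$passed <- r$passed
    out
  }))
}

#' Run one testing-stage method on a gene
#'
#' Dispatches per method name (see [testingMethods]). Covariates are the
#' intercept, age, sex, the two population-structure PCs, and the
#' environment exposure; the exposure also drives the interaction block of
#' the logistic score test and the gene-environment kernel. Madsen-Browning
#' weights and summary-score coefficients are estimated on `weightSource`
#' (the paired screening replicate in the two-stage pipeline) and applied to
#' `x`'s genotypes.
#'
#' @param x testing-stage `SnpSetExperiment` (needs `status`, `age`, `sex`,
#'   `environment`, `pc1`, `pc2`).
#' @param gene gene symbol.
#' @param method one of [testingMethods].
#' @param weightSource dataset supplying weights/coefficients; defaults to `x`.
#' @return a [TestResult-class] with the method name as label.
#' @export
testGene <- function(x, gene, method, weightSource = x) {
  if (!method %in% testingMethods)
    stop("unknown testing method: ", method)
  si <- sampleInfo(x)
  needed <- c("status", "age", "sex", "environment", "pc1", "pc2")
  missing <- setdiff(needed, colnames(si))
  if (length(missing))
    stop("sample table lacks column(s): ", paste(missing, collapse = ", "))
  y <- si$status
  s <- si$environment
  X <- cbind(intercept = 1, age = si$age, sex = si$sex,
             pc1 = si$pc1, pc2 = si$pc2, smoke = s)

  cs <- collapseGene(x, gene, weightSource = weightSource)
  sub <- geneSubset(x, gene)
  rd <- SummarizedExperiment::rowData(sub)
  commonIds <- rownames(sub)[rd$frequency_class == "common"]
  gC <- if (length(commonIds))
    meanImpute(genoMatrix(sub)[, commonIds, drop = FALSE]) else NULL

  res <- switch(method,
    logistic_regression = {
      Z <- cbind(gC, ws_combined = cs@wsCombined)
      logisticScoreTest(y, X, Z, s = s)
    },
    logistic_common_score = {
      Z <- if (length(cs@commonScore))
        cbind(common_score = cs@commonScore, ws_combined = cs@wsCombined)
      else cbind(ws_combined = cs@wsCombined)
      logisticScoreTest(y, X, Z, s = s)
    },
    linear_rare_ws_combined =
      kernelMachineTest(y, X, cbind(gC, cs@wsCombined), s = s, kernel = "linear"),
    linear_rare_ws_nonsyn =
      kernelMachineTest(y, X, cbind(gC, cs@wsNonsyn), s = s, kernel = "linear"),
    quadratic_rare_ws_combined =
      kernelMachineTest(y, X, cbind(gC, cs@wsCombined), s = s, kernel = "quadratic"))
  res@method <- method
  res
}

#' Holm step-down familywise error adjustment
#'
#' Sorts the p-values ascending, multiplies the i-th smallest by
#' `m - i + 1`, enforces monotonicity, caps at 1 and maps back to the input
#' order (`stats::p.adjust`, method `"holm"`).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
holmAdjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Run the two-stage screening/testing pipeline over replicate pairs
#'
#' For each (screening, testing) replicate pair: every gene is screened on
#' the screening replicate ([screenGene()]); each testing method is applied
#' to the genes that passed, with weights taken from the screening
#' replicate; within each method the p-values are Holm-adjusted across the
#' screened-in genes and a gene is selected when its adjusted p-value falls
#' below `alphaSelect`. Counts are aggregated across pairs. With
#' `screening = FALSE` every gene proceeds to testing (the comparison arm
#' for measuring how screening suppresses false positives).
#'
#' @param pairs list of `list(screen = , test = )` `SnpSetExperiment` pairs
#'   sharing variant and gene definitions (e.g. from [generateReplicates()]).
#' @param threshold screening p-value cutoff (default 0.1).
#' @param alphaSelect adjusted-p selection cutoff (default 0.1).
#' @param B screening permutations per test (default 1000).
#' @param methods testing methods to run (default all five).
#' @param screening logical; `FALSE` bypasses the screening stage.
#' @param seed master seed; per-pair streams are derived from it.
#' @return data.frame with columns `gene`, `method`, `times_selected`,
#'   `times_screened_in`.
#' @export
runTwoStage <- function(pairs, threshold = 0.1, alphaSelect = 0.1, B = 1000,
                        methods = testingMethods, screening = TRUE, seed = 1) {
  tally <- NULL
  for (i in seq_along(pairs)) {
    scr <- pairs[[i]]$screen
    tst <- pairs[[i]]$test
    genes <- names(snpSets(scr))
    if (!identical(genes, names(snpSets(tst))))
      stop("pair ", i, ": gene sets differ between screening and testing data")
    for (obj in c("scr", "tst")) {
      o <- get(obj)
      if (!"pc1" %in% colnames(SummarizedExperiment::colData(o)))
        assign(obj, computePopulationPCs(o))
    }
    if (is.null(tally)) {
      tally <- expand.grid(gene = genes, method = methods,
                           stringsAsFactors = FALSE)
      tally$times_selected <- 0L
      tally$times_screened_in <- 0L
    }
    set.seed((seed * 7919 + i * 104729) %% .Machine$integer.max)
    passed <- if (screening) {
      keep <- vapply(genes, function(g)
        screenGene(scr, g, threshold = threshold, B = B)$passed, logical(1))
      genes[keep]
    } else genes
    if (!length(passed)) next
    tally$times_screened_in <- tally$times_screened_in +
      as.integer(tally$gene %in% passed)
    for (m in methods) {
      ps <- vapply(passed, function(g)
        tryCatch(pValue(testGene(tst, g, m, weightSource = scr)),
                 error = function(e) NA_real_), numeric(1))
      ok <- !is.na(ps)
      if (!any(ok)) next
      adj <- holmAdjust(ps[ok])
      sel <- names(ps)[ok][adj < alphaSelect]
      tally$times_selected <- tally$times_selected +
        as.integer(tally$method == m & tally$gene %in% sel)
    }
  }
  tally
}
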