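#' Madsen-Browning weights for rare variants
#'
#' Each variant's weight is proportional to its estimated standard deviation
#' in the population, with the minor allele frequency estimated from the
#' unaffected samples under a +1/+2 pseudocount:
#' `q_k = (m_k^U + 1) / (2 n_k^U + 2)`, where `m_k^U` is the minor-allele
#' count among unaffected samples and `n_k^U` the number of unaffected
#' samples with a non-missing genotype, and
#' `w_k = sqrt(n_k q_k (1 - q_k))` with `n_k` the total number of genotyped
#' samples. The pseudocount keeps weights finite and positive for variants
#' absent from the controls. Scores divide by `w_k`, so rarer variants
#' contribute more.
#'
#' @param g samples x variants genotype matrix (one functional class of a
#'   gene's rare variants).
#' @param status binary phenotype (0 unaffected, 1 affected) aligned with
#'   the rows of `g`.
#' @return named numeric vector of weights, one per variant.
#' @export
madsenBrowningWeights <- function(g, status) {
  g <- as.matrix(g)
  stopifnot(length(status) == nrow(g))
  unaff <- which(status == 0)
  if (!length(unaff)) stop("no unaffected samples: weights undefined")
  gu <- g[unaff, , drop = FALSE]
  mU <- colSums(gu, na.rm = TRUE)
  nU <- colSums(!is.na(gu))
  q <- (mU + 1) / (2 * nU + 2)
  n <- colSums(!is.na(g))
  w <- sqrt(n * q * (1 - q))
  names(w) <- colnames(g)
  w
}

#' Weighted-sum scores of a gene's rare variants by functional class
#'
#' For each sample, `score_i = sum_k I_ik / w_k` over the gene's rare
#' variants of the given class, with Madsen-Browning weights. The dataset
#' supplying the weights is an explicit argument so that, in the two-stage
#' pipeline, weights can come from the screening replicate while scores are
#' evaluated on the testing replicate. An empty class yields a zero score.
#'
#' @param x `SnpSetExperiment` with `frequency_class` filled, restricted or
#'   not; scores are computed for `gene`'s variants.
#' @param gene gene symbol.
#' @param weightSource `SnpSetExperiment` used to estimate the weights
#'   (defaults to `x`). Must contain the same variants and a `status` column.
#' @param weightStatus optional status vector overriding
#'   `sampleInfo(weightSource)$status` (used by permutation tests).
#' @return `list(wsSyn, wsNonsyn, weights)` with per-sample scores and the
#'   per-class weight vectors.
#' @export
weightedSumScores <- function(x, gene, weightSource = x, weightStatus = NULL) {
  sub <- geneSubset(x, gene)
  rd <- SummarizedExperiment::rowData(sub)
  if (!"frequency_class" %in% colnames(rd))
    stop("run classifyVariantFrequency() first")
  n <- ncol(sub)
  if (is.null(weightStatus)) weightStatus <- sampleInfo(weightSource)$status
  out <- list(wsSyn = numeric(n), wsNonsyn = numeric(n),
              weights = list(synonymous = numeric(0), nonsynonymous = numeric(0)))
  gAll <- genoMatrix(sub)
  gw <- genoMatrix(weightSource)
  for (cls in c("synonymous", "nonsynonymous")) {
    ids <- rownames(sub)[rd$frequency_class == "rare" & rd$functional_class == cls]
    if (!length(ids)) next
    w <- madsenBrowningWeights(gw[, ids, drop = FALSE], weightStatus)
    sc <- drop(meanImpute(gAll[, ids, drop = FALSE]) %*% (1 / w))
    if (cls == "synonymous") out$wsSyn <- sc else out$wsNonsyn <- sc
    out$weights[[cls]] <- w
  }
  names(out$wsSyn) <- names(out$wsNonsyn) <- colnames(sub)
  out
}

#' Combine the class-specific weighted-sum scores
#'
#' `WS_combined = WS_syn + 2 WS_nonsyn`: nonsynonymous variants, being more
#' likely functional, receive double weight.
#'
#' @param wsSyn,wsNonsyn equal-length per-sample score vectors.
#' @return per-sample combined score.
#' @export
combinedWS <- function(wsSyn, wsNonsyn) {
  if (length(wsSyn) != length(wsNonsyn))
    stop("score vectors differ in length")
  wsSyn + 2 * wsNonsyn
}

#' Case/control allele-frequency-contrast coefficients
#'
#' The default coefficient function for [commonSummaryScore()]:
#' `c_k = m_k^A / (2 n_k^A) - m_k^U / (2 n_k^U)`, the difference in estimated
#' minor allele frequency between affected and unaffected samples (the fitted
#' principal-component direction for a binary response, without covariance
#' rescaling). Counts use non-missing genotypes per variant.
#'
#' @param g samples x variants genotype matrix.
#' @param status binary phenotype aligned with rows of `g`.
#' @return named numeric coefficient vector.
#' @export
freqContrastCoeffs <- function(g, status) {
  aff <- which(status == 1); unaff <- which(status == 0)
  if (!length(aff) || !length(unaff))
    stop("both affected and unaffected samples are required")
  gA <- g[aff, , drop = FALSE]; gU <- g[unaff, , drop = FALSE]
  cf <- colSums(gA, na.rm = TRUE) / (2 * colSums(!is.na(gA))) -
        colSums(gU, na.rm = TRUE) / (2 * colSums(!is.na(gU)))
  names(cf) <- colnames(g)
  cf
}

#' Summary score for a gene's common variants
#'
#' One-dimensional reduction of the common variants,
#' `score_i = sum_k c_k I_ik`, with coefficients contrasting the affected and
#' unaffected allele frequencies (principal fitted components idea). The
#' coefficient function is pluggable.
#'
#' @param g samples x variants genotype matrix restricted to a gene's common
#'   variants.
#' @param status binary phenotype used to derive the coefficients.
#' @param coefFn function `(g, status) -> coefficients`; defaults to
#'   [freqContrastCoeffs()].
#' @return `list(score, coeffs)`.
#' @export
commonSummaryScore <- function(g, status, coefFn = freqContrastCoeffs) {
  g <- as.matrix(g)
  if (ncol(g) < 1) stop("no common variants supplied")
  cf <- coefFn(g, status)
  list(score = drop(meanImpute(g) %*% cf), coeffs = cf)
}

#' Collapse one gene into its per-sample scores
#'
#' Computes the rare-variant weighted-sum scores by functional class, their
#' combination, and the common-variant summary score (empty when the gene
#' has no common variants).
#'
#' @param x `SnpSetExperiment` with `frequency_class` filled and a `status`
#'   sample column.
#' @param gene gene symbol.
#' @param weightSource dataset supplying the Madsen-Browning weights and the
#'   summary-score coefficients; defaults to `x`.
#' @return a [CollapsedScores-class] object.
#' @export
collapseGene <- function(x, gene, weightSource = x) {
  ws <- weightedSumScores(x, gene, weightSource = weightSource)
  sub <- geneSubset(x, gene)
  rd <- SummarizedExperiment::rowData(sub)
  commonIds <- rownames(sub)[rd$frequency_class == "common"]
  commonScore <- numeric(0)
  coeffs <- numeric(0)
  if (length(commonIds)) {
    gw <- genoMatrix(weightSource)[, commonIds, drop = FALSE]
    cf <- freqContrastCoeffs(gw, sampleInfo(weightSource)$status)
    commonScore <- drop(meanImpute(genoMatrix(sub)[, commonIds, drop = FALSE]) %*% cf)
    coeffs <- cf
  }
  methods::new("CollapsedScores", gene = gene,
               wsSyn = unname(ws$wsSyn), wsNonsyn = unname(ws$wsNonsyn),
               wsCombined = unname(combinedWS(ws$wsSyn, ws$wsNonsyn)),
               commonScore = unname(commonScore),
               weightsRare = ws$weights, coeffsCommon = coeffs)
}

#' Export collapsed scores as a data.frame
#'
#' @param scores a [CollapsedScores-class] object.
#' @param sampleIds sample identifiers.
#' @return data.frame with columns sample_id, gene, ws_syn, ws_nonsyn,
#'   ws_combined, common_score.
#' @export
collapsedScoresTable <- function(scores, sampleIds) {
  data.frame(sample_id = sampleIds, gene = scores@gene,
             ws_syn = scores@wsSyn, ws_nonsyn = scores@wsNonsyn,
             ws_combined = scores@wsCombined,
             common_score = if (length(scores@commonScore)) scores@commonScore
                            else NA_real_,
             stringsAsFactors = FALSE)
}
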