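#' SnpSetExperiment: genotypes, variant annotation and sample data for SNP-set tests
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding an
#' additive-coded genotype matrix in the `"geno"` assay (variants as rows,
#' samples as columns; entries count minor alleles, 0/1/2, `NA` allowed),
#' per-variant annotation in `rowData()` (`gene`, `functional_class`, and --
#' once computed -- `maf`, `frequency_class`, optionally `chrom`/`pos`), and
#' per-sample data in `colData()` (`status`, `age`, `sex`, `environment`,
#' optionally `subpopulation`, `pc1`, `pc2`).
#'
#' A SNP set is the ordered group of variants annotated to one gene; row order
#' of the object defines within-set variant order.
#'
#' @slot .. inherited from SummarizedExperiment.
#' @seealso [SnpSetExperiment()] for the constructor, [genoMatrix()],
#'   [variantInfo()], [sampleInfo()], [snpSets()].
#' @export
setClass("SnpSetExperiment", contains = "SummarizedExperiment")

.validSnpSetExperiment <- function(object) {
  msg <- character()
  if (!"geno" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'geno' is required")
  else {
    g <- SummarizedExperiment::assay(object, "geno")
    vals <- g[!is.na(g)]
    if (length(vals) && !all(vals %in% c(0L, 1L, 2L)))
      msg <- c(msg, "non-missing genotype entries must be 0, 1 or 2")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "variant ids (rownames) must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be unique")
  rd <- SummarizedExperiment::rowData(object)
  if ("functional_class" %in% colnames(rd)) {
    fc <- rd$functional_class
    if (!all(fc %in% c("synonymous", "nonsynonymous")))
      msg <- c(msg, "functional_class must be 'synonymous' or 'nonsynonymous'")
  }
  cd <- SummarizedExperiment::colData(object)
  if ("status" %in% colnames(cd)) {
    st <- cd$status
    if (!all(is.na(st) | st %in% c(0, 1)))
      msg <- c(msg, "status must be binary (0 unaffected, 1 affected)")
  }
  if (length(msg)) msg else TRUE
}

setValidity("SnpSetExperiment", .validSnpSetExperiment)

#' Construct a SnpSetExperiment
#'
#' @param geno integer matrix of minor-allele counts, samples in rows and
#'   variants in columns (the orientation of the tabular genotype dialect);
#'   it is stored transposed, following the Bioconductor convention of
#'   features (variants) as rows. Dimnames are required.
#' @param variants `data.frame` of per-variant annotation with a `variant_id`
#'   column matching `colnames(geno)`; typically also `gene` and
#'   `functional_class`. Order is taken from `geno`, not from `variants`.
#' @param samples `data.frame` of per-sample data with a `sample_id` column
#'   matching `rownames(geno)`.
#' @return A [SnpSetExperiment-class] object.
#' @examples
#' g <- matrix(c(0L, 1L, 2L, 0L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("v1", "v2")))
#' ann <- data.frame(variant_id = c("v1", "v2"), gene = "G1",
#'                   functional_class = c("synonymous", "nonsynonymous"))
#' sam <- data.frame(sample_id = c("s1", "s2"), status = c(0L, 1L))
#' SnpSetExperiment(g, ann, sam)
#' @export
SnpSetExperiment <- function(geno, variants = NULL, samples = NULL) {
  geno <- as.matrix(geno)
  if (is.null(rownames(geno)) || is.null(colnames(geno)))
    stop("'geno' needs sample ids as rownames and variant ids as colnames")
  storage.mode(geno) <- "integer"
  rd <- S4Vectors::DataFrame(row.names = colnames(geno))
  if (!is.null(variants)) {
    if (!"variant_id" %in% colnames(variants))
      stop("'variants' must have a 'variant_id' column")
    idx <- match(colnames(geno), variants$variant_id)
    if (anyNA(idx))
      stop("variants missing from annotation: ",
           paste(utils::head(colnames(geno)[is.na(idx)], 5), collapse = ", "))
    rd <- S4Vectors::DataFrame(variants[idx, setdiff(colnames(variants), "variant_id"),
                                        drop = FALSE],
                               row.names = colnames(geno))
  }
  cd <- S4Vectors::DataFrame(row.names = rownames(geno))
  if (!is.null(samples)) {
    if (!"sample_id" %in% colnames(samples))
      stop("'samples' must have a 'sample_id' column")
    idx <- match(rownames(geno), samples$sample_id)
    if (anyNA(idx))
      stop("samples missing from sample table: ",
           paste(utils::head(rownames(geno)[is.na(idx)], 5), collapse = ", "))
    cd <- S4Vectors::DataFrame(samples[idx, setdiff(colnames(samples), "sample_id"),
                                       drop = FALSE],
                               row.names = rownames(geno))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(geno = t(geno)), rowData = rd, colData = cd)
  methods::new("SnpSetExperiment", se)
}

setMethod("show", "SnpSetExperiment", function(object) {
  cat("SnpSetExperiment:", nrow(object), "variants x", ncol(object), "samples\n")
  rd <- SummarizedExperiment::rowData(object)
  if ("gene" %in% colnames(rd))
    cat("  SNP sets (genes):", length(unique(rd$gene)), "\n")
  if ("frequency_class" %in% colnames(rd))
    cat("  rare variants:", sum(rd$frequency_class == "rare"),
        "| common:", sum(rd$frequency_class == "common"), "\n")
  cd <- SummarizedExperiment::colData(object)
  if ("status" %in% colnames(cd) && !anyNA(cd$status))
    cat("  affected:", sum(cd$status == 1), "| unaffected:", sum(cd$status == 0), "\n")
  invisible(object)
})

#' Per-gene collapsed scores for one SNP set
#'
#' Holds the Madsen-Browning weighted-sum scores by functional class, their
#' fixed 1:2 combination (nonsynonymous variants weighted double), and the
#' principal-fitted-components summary score of the gene's common variants.
#'
#' @slot gene gene symbol.
#' @slot wsSyn,wsNonsyn,wsCombined per-sample weighted-sum scores of rare
#'   synonymous / nonsynonymous variants; `wsCombined == wsSyn + 2 * wsNonsyn`.
#' @slot commonScore per-sample common-variant summary score (length 0 when
#'   the gene has no common variants).
#' @slot weightsRare named list with per-variant Madsen-Browning weights for
#'   the `synonymous` and `nonsynonymous` classes.
#' @slot coeffsCommon per-variant summary-score coefficients.
#' @export
setClass("CollapsedScores",
  representation(gene = "character", wsSyn = "numeric", wsNonsyn = "numeric",
                 wsCombined = "numeric", commonScore = "numeric",
                 weightsRare = "list", coeffsCommon = "numeric"))

setValidity("CollapsedScores", function(object) {
  msg <- character()
  n <- length(object@wsSyn)
  if (length(object@wsNonsyn) != n || length(object@wsCombined) != n)
    msg <- c(msg, "score vectors must share one length")
  else if (n && max(abs(object@wsCombined - (object@wsSyn + 2 * object@wsNonsyn))) > 1e-8)
    msg <- c(msg, "wsCombined must equal wsSyn + 2 * wsNonsyn")
  if (length(object@commonScore) && length(object@commonScore) != n)
    msg <- c(msg, "commonScore length must match the other scores")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CollapsedScores", function(object) {
  cat("CollapsedScores for gene", object@gene, "-", length(object@wsSyn), "samples\n")
  cat("  rare weights: syn", length(object@weightsRare$synonymous),
      "| nonsyn", length(object@weightsRare$nonsynonymous),
      "| common coefficients:", length(object@coeffsCommon), "\n")
  invisible(object)
})

#' Result of a single association test
#'
#' @slot method label of the test performed.
#' @slot statistic observed test statistic.
#' @slot df degrees of freedom of the reference distribution (`NA` when the
#'   p-value is permutation-based or moment-matched).
#' @slot moments named numeric of moment-match parameters
#'   (`kappa1`, `nu1`, `kappa2`, `nu2`) for kernel machine tests; empty otherwise.
#' @slot pValue p-value in `[0, 1]` (`NA` when only a statistic is available).
#' @slot pSource `"analytic"` or `"permutation"`.
#' @slot nUsed number of samples used.
#' @slot notes diagnostics (dropped columns, rank deficiency, ...).
#' @export
setClass("TestResult",
  representation(method = "character", statistic = "numeric", df = "numeric",
                 moments = "numeric", pValue = "numeric", pSource = "character",
                 nUsed = "integer", notes = "character"))

setValidity("TestResult", function(object) {
  msg <- character()
  p <- object@pValue
  if (length(p) && !is.na(p) && (p < 0 || p > 1))
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (length(object@df) && !is.na(object@df) && object@df <= 0)
    msg <- c(msg, "df must be positive where present")
  if (length(msg)) msg else TRUE
})

.TestResult <- function(method, statistic, df = NA_real_, moments = numeric(),
                        pValue = NA_real_, pSource = "analytic",
                        nUsed = NA_integer_, notes = character()) {
  methods::new("TestResult", method = method, statistic = statistic,
               df = as.numeric(df), moments = moments, pValue = as.numeric(pValue),
               pSource = pSource, nUsed = as.integer(nUsed), notes = notes)
}

setMethod("show", "TestResult", function(object) {
  cat(sprintf("TestResult [%s]: statistic = %.5g", object@method, object@statistic))
  if (!is.na(object@df)) cat(sprintf(", df = %g", object@df))
  if (!is.na(object@pValue))
    cat(sprintf(", p = %.4g (%s)", object@pValue, object@pSource))
  cat("\n")
  if (length(object@moments))
    cat("  moments:", paste(names(object@moments),
                            signif(object@moments, 4), sep = "=", collapse = ", "), "\n")
  if (length(object@notes)) cat("  notes:", paste(object@notes, collapse = "; "), "\n")
  invisible(object)
})

#' Variance-component score statistics for a kernel machine test
#'
#' The two quadratic-form components of the score statistic: the main genetic
#' component (kernel `K`) and the gene-environment component (kernel `Ktilde`),
#' with their null means/variances under the efficient projection and the
#' scale/df parameters of the matched scaled chi-square approximations.
#'
#' @slot qTau,qTauTilde quadratic-form score components (>= 0).
#' @slot moments 2x2 matrix, rows `tau`/`tauTilde`, columns `mean`/`variance`.
#' @slot kappa,nu scale and degrees of freedom of each scaled chi-square
#'   approximation (NA for a degenerate component).
#' @slot degenerate logical flags: component variance at machine zero.
#' @slot nUsed sample count.
#' @export
setClass("QComponents",
  representation(qTau = "numeric", qTauTilde = "numeric", moments = "matrix",
                 kappa = "numeric", nu = "numeric", degenerate = "logical",
                 nUsed = "integer"))

setValidity("QComponents", function(object) {
  msg <- character()
  if (!is.na(object@qTau) && object@qTau < -1e-8)
    msg <- c(msg, "qTau must be non-negative")
  ok <- !object@degenerate & !is.na(object@kappa)
  if (any(ok & (object@kappa <= 0 | object@nu <= 0)))
    msg <- c(msg, "kappa and nu must be positive for non-degenerate components")
  if (length(msg)) msg else TRUE
})

setMethod("show", "QComponents", function(object) {
  cat(sprintf("QComponents: qTau = %.5g, qTauTilde = %.5g\n",
              object@qTau, object@qTauTilde))
  print(signif(object@moments, 5))
  invisible(object)
})

#' Null logistic model fit used by score and kernel machine tests
#'
#' @slot coef coefficient estimates for the covariate matrix `X`.
#' @slot fitted fitted probabilities, strictly inside (0, 1).
#' @slot weights working weights `fitted * (1 - fitted)`.
#' @slot X the covariate design matrix (including the intercept).
#' @export
setClass("NullFit",
  representation(coef = "numeric", fitted = "numeric", weights = "numeric",
                 X = "matrix"))

setValidity("NullFit", function(object) {
  if (any(object@fitted <= 0 | object@fitted >= 1))
    return("fitted probabilities must lie strictly in (0, 1)")
  TRUE
})

setMethod("show", "NullFit", function(object) {
  cat("NullFit:", length(object@fitted), "samples,",
      ncol(object@X), "covariates\n")
  invisible(object)
})
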