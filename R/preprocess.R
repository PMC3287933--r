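#' @describeIn SnpSetTest-generics minor allele frequencies from a samples x
#'   variants genotype matrix. Missing entries are excluded per variant;
#'   frequencies are folded to `min(f, 1 - f)` so the result lies in
#'   `[0, 0.5]`. A variant with all entries missing is an error.
#' @export
setMethod("computeMaf", "matrix", function(x) {
  nn <- colSums(!is.na(x))
  if (any(nn == 0)) {
    bad <- colnames(x)[nn == 0]
    if (is.null(bad)) bad <- which(nn == 0)
    stop("variant(s) with all genotypes missing: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  f <- colSums(x, na.rm = TRUE) / (2 * nn)
  maf <- pmin(f, 1 - f)
  names(maf) <- colnames(x)
  maf
})

#' @describeIn SnpSetTest-generics fill `rowData()$maf` of a `SnpSetExperiment`.
#' @export
setMethod("computeMaf", "SnpSetExperiment", function(x) {
  SummarizedExperiment::rowData(x)$maf <- unname(computeMaf(genoMatrix(x)))
  x
})

#' @describeIn SnpSetTest-generics classify minor allele frequencies as
#'   `"rare"` (strictly below `threshold`, default 1%) or `"common"`.
#' @param threshold rare/common MAF boundary; variants with `maf < threshold`
#'   are rare, all others (including `maf == threshold`) common.
#' @export
setMethod("classifyVariantFrequency", "numeric", function(x, threshold = 0.01) {
  stopifnot(all(x >= 0 & x <= 0.5))
  ifelse(x < threshold, "rare", "common")
})

#' @describeIn SnpSetTest-generics fill `rowData()$frequency_class`
#'   (requires `maf`).
#' @export
setMethod("classifyVariantFrequency", "SnpSetExperiment",
          function(x, threshold = 0.01) {
  rd <- SummarizedExperiment::rowData(x)
  if (!"maf" %in% colnames(rd)) stop("run computeMaf() first")
  SummarizedExperiment::rowData(x)$frequency_class <-
    classifyVariantFrequency(rd$maf, threshold)
  x
})

#' @describeIn SnpSetTest-generics drop variants carried by at most one
#'   sample. A carrier is a sample with at least one minor allele; variants
#'   with zero carriers (monomorphic) are dropped too, as they carry no
#'   association information and break standardization. Returns
#'   `list(genotypes, removed)` for a matrix.
#' @export
setMethod("filterSingletonVariants", "matrix", function(x) {
  carriers <- colSums(x >= 1, na.rm = TRUE)
  keep <- carriers >= 2
  removed <- colnames(x)[!keep]
  if (!any(keep)) warning("all variants removed; empty genotype matrix")
  list(genotypes = x[, keep, drop = FALSE], removed = removed)
})

#' @describeIn SnpSetTest-generics same filter on a `SnpSetExperiment`;
#'   returns `list(object, removed)`.
#' @export
setMethod("filterSingletonVariants", "SnpSetExperiment", function(x) {
  carriers <- colSums(genoMatrix(x) >= 1, na.rm = TRUE)
  keep <- carriers >= 2
  if (!any(keep)) warning("all variants removed; empty object")
  list(object = x[keep, ], removed = rownames(x)[!keep])
})

#' Remove genes whose rare variants are carried by too few samples
#'
#' A gene is removed when fewer than `minCarrierFrac` of the samples carry at
#' least one minor allele across the gene's rare variants. Genes with no rare
#' variants are retained: the burden rule is vacuous for them and their common
#' variants remain testable.
#'
#' @param x a `SnpSetExperiment` with `frequency_class` filled.
#' @param minCarrierFrac minimum carrier fraction (default 0.01).
#' @return `list(object, removed)` -- the object restricted to retained genes
#'   and the removed gene symbols.
#' @export
filterLowBurdenGenes <- function(x, minCarrierFrac = 0.01) {
  rd <- SummarizedExperiment::rowData(x)
  if (!"frequency_class" %in% colnames(rd))
    stop("run classifyVariantFrequency() first")
  g <- genoMatrix(x)
  sets <- snpSets(x)
  rare <- rownames(x)[rd$frequency_class == "rare"]
  removed <- character()
  for (gene in names(sets)) {
    vr <- intersect(sets[[gene]], rare)
    if (!length(vr)) next
    carrier <- rowSums(g[, vr, drop = FALSE] >= 1, na.rm = TRUE) > 0
    if (mean(carrier) < minCarrierFrac) removed <- c(removed, gene)
  }
  keep <- !(as.character(rd$gene) %in% removed)
  list(object = x[keep, ], removed = removed)
}

#' Standardize matrix columns to mean 0 and unit standard deviation
#'
#' Uses the n - 1 denominator. Constant columns are mean-centered only (all
#' zeros) and flagged in the `"constant"` attribute.
#'
#' @param m numeric matrix.
#' @return matrix of the same shape with a logical `"constant"` attribute.
#' @export
standardizeColumns <- function(m) {
  m <- as.matrix(m)
  mu <- colMeans(m)
  centered <- sweep(m, 2, mu)
  sds <- sqrt(colSums(centered^2) / max(1, nrow(m) - 1))
  const <- !is.finite(sds) | sds < 1e-12
  if (any(!const))
    centered[, !const] <- sweep(centered[, !const, drop = FALSE], 2,
                                sds[!const], "/")
  attr(centered, "constant") <- const
  centered
}

#' Impute missing genotypes to the per-variant mean
#'
#' Keeps additive dosage semantics at test time; MAF estimation always uses
#' non-missing entries only.
#'
#' @param g samples x variants genotype matrix.
#' @return numeric matrix with no missing values.
#' @export
meanImpute <- function(g) {
  g <- as.matrix(g) * 1.0
  if (!anyNA(g)) return(g)
  mu <- colMeans(g, na.rm = TRUE)
  idx <- which(is.na(g), arr.ind = TRUE)
  g[idx] <- mu[idx[, 2]]
  g
}

.pcSelectVariants <- function(maf, chrom, pos, mafMin, minSpacing) {
  eligible <- maf > mafMin
  if (is.null(minSpacing)) return(which(eligible))
  if (is.null(pos)) stop("variant positions required for the spacing filter")
  if (is.null(chrom)) chrom <- rep(1L, length(pos))
  keep <- logical(length(maf))
  for (ch in unique(chrom)) {
    idx <- which(eligible & chrom == ch)
    idx <- idx[order(pos[idx])]
    last <- -Inf
    for (i in idx) {                      # greedy left-to-right scan
      if (pos[i] - last >= minSpacing) {
        keep[i] <- TRUE
        last <- pos[i]
      }
    }
  }
  which(keep)
}

#' @describeIn SnpSetTest-generics population-structure principal components
#'   from a samples x variants genotype matrix. Variants with
#'   `maf > mafMin` (and, when `minSpacing` and positions are given, pairwise
#'   distance at least `minSpacing` by a greedy scan in position order) are
#'   mean-centered and the top `k` left singular scores returned. Each PC's
#'   sign is fixed so its loading vector has non-negative sum.
#' @param mafMin minimum MAF (strict) for a variant to enter the PCA;
#'   default 0.10.
#' @param minSpacing minimum base-pair spacing between retained variants
#'   (`NULL` disables the filter).
#' @param k number of components (default 2).
#' @param chrom,pos per-variant chromosome and position (needed for spacing).
#' @export
setMethod("computePopulationPCs", "matrix",
          function(x, mafMin = 0.10, minSpacing = NULL, k = 2,
                   chrom = NULL, pos = NULL) {
  maf <- computeMaf(x)
  sel <- .pcSelectVariants(maf, chrom, pos, mafMin, minSpacing)
  if (length(sel) < k)
    stop("fewer than k = ", k, " variants eligible for PCA")
  m <- meanImpute(x[, sel, drop = FALSE])
  m <- sweep(m, 2, colMeans(m))
  sv <- svd(m, nu = k, nv = k)
  flip <- ifelse(colSums(sv$v) < 0, -1, 1)
  scores <- sv$u %*% diag(sv$d[seq_len(k)] * flip, k)
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("pc", seq_len(k))
  scores
})

#' @describeIn SnpSetTest-generics compute PCs from the genotypes and fill
#'   `colData()$pc1 ... pck`; chromosome/position are taken from `rowData()`
#'   when present.
#' @export
setMethod("computePopulationPCs", "SnpSetExperiment",
          function(x, mafMin = 0.10, minSpacing = NULL, k = 2) {
  rd <- SummarizedExperiment::rowData(x)
  scores <- computePopulationPCs(genoMatrix(x), mafMin = mafMin,
                                 minSpacing = minSpacing, k = k,
                                 chrom = if ("chrom" %in% colnames(rd)) rd$chrom,
                                 pos = if ("pos" %in% colnames(rd)) rd$pos)
  for (j in seq_len(k))
    SummarizedExperiment::colData(x)[[paste0("pc", j)]] <- scores[, j]
  x
})
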