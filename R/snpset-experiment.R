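#' @describeIn SnpSetExperiment genotype matrix, samples in rows and variants
#'   in columns (the orientation used by the statistical routines).
#' @param x a `SnpSetExperiment`.
#' @export
setMethod("genoMatrix", "SnpSetExperiment", function(x) {
  t(SummarizedExperiment::assay(x, "geno"))
})

#' @describeIn SnpSetExperiment per-variant annotation as a `data.frame` with
#'   a `variant_id` column.
#' @export
setMethod("variantInfo", "SnpSetExperiment", function(x) {
  rd <- as.data.frame(SummarizedExperiment::rowData(x))
  cbind(data.frame(variant_id = rownames(x), stringsAsFactors = FALSE), rd)
})

#' @describeIn SnpSetExperiment per-sample data as a `data.frame` with a
#'   `sample_id` column.
#' @export
setMethod("sampleInfo", "SnpSetExperiment", function(x) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  cbind(data.frame(sample_id = colnames(x), stringsAsFactors = FALSE), cd)
})

#' @describeIn SnpSetExperiment named list of SNP sets: variant ids split by
#'   gene, preserving row (file) order within each gene and first-appearance
#'   order of genes.
#' @export
setMethod("snpSets", "SnpSetExperiment", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if (!"gene" %in% colnames(rd))
    stop("rowData has no 'gene' column; supply variant annotation first")
  gene <- as.character(rd$gene)
  split(rownames(x), factor(gene, levels = unique(gene)))
})

#' Subset a SnpSetExperiment to the variants of one gene
#'
#' @param x a `SnpSetExperiment`.
#' @param gene gene symbol.
#' @return a `SnpSetExperiment` restricted to that gene's variants.
#' @export
geneSubset <- function(x, gene) {
  rd <- SummarizedExperiment::rowData(x)
  keep <- which(as.character(rd$gene) == gene)
  if (!length(keep)) stop("gene not present: ", gene)
  x[keep, ]
}
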