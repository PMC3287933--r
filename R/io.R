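#' Read a genotype matrix from VCF or the tabular dialect
#'
#' Genotypes are returned as additive minor-allele counts (0/1/2, `NA`
#' allowed), samples in rows and variants in columns. For VCF input only the
#' GT field is used and genotypes must be diploid; the minor allele of each
#' variant is determined from the sample allele frequencies, not from the
#' REF/ALT orientation, so a variant whose ALT frequency exceeds 0.5 is
#' recoded to count REF alleles.
#'
#' The tabular dialect is a TSV with a header, first column `sample_id`, the
#' remaining columns one variant each, cells 0/1/2 or `NA`.
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"`.
#' @return integer matrix with sample rownames and variant colnames.
#' @seealso [writeGenotypes()] for the inverse of the TSV reader.
#' @export
readGenotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") .readGenotypesTsv(path) else .readGenotypesVcf(path)
}

.readGenotypesTsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1] != "sample_id")
    stop("first column of the genotype table must be 'sample_id'")
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in genotype table")
  g <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(g) <- "integer"
  bad <- which(!is.na(g) & !(g %in% 0:2), arr.ind = TRUE)
  if (nrow(bad))
    stop("parse error at data line ", bad[1, 1], ": genotype entries must be 0, 1, 2 or NA")
  rownames(g) <- df$sample_id
  g
}

.readGenotypesVcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt) || nrow(gt) == 0) stop("no genotypes found in VCF: ", path)
  ids <- rownames(gt)
  if (is.null(ids) || anyNA(ids) || any(ids == "."))
    ids <- paste0(vcf@fix[, "CHROM"], ":", vcf@fix[, "POS"])
  alleles <- gsub("\\|", "/", gt)
  alleles[alleles %in% c(".", "./.", ".|.")] <- NA
  parts <- strsplit(alleles, "/", fixed = TRUE)
  nall <- lengths(parts)
  badPloidy <- !is.na(alleles) & nall != 2
  if (any(badPloidy)) {
    v <- ids[which(rowSums(matrix(badPloidy, nrow(gt))) > 0)[1]]
    stop("non-diploid genotype at variant ", v)
  }
  dose <- vapply(parts, function(a) {
    if (length(a) != 2 || anyNA(a) || any(a == ".")) return(NA_integer_)
    sum(a != "0")
  }, integer(1))
  dose <- matrix(dose, nrow = nrow(gt), dimnames = list(ids, colnames(gt)))
  # orient each variant to count its minor allele
  af <- rowSums(dose, na.rm = TRUE) / (2 * rowSums(!is.na(dose)))
  flip <- !is.na(af) & af > 0.5
  dose[flip, ] <- 2L - dose[flip, ]
  t(dose)
}

#' Write a genotype matrix in the tabular dialect
#'
#' @param g samples x variants integer matrix with dimnames.
#' @param path output TSV path.
#' @export
writeGenotypes <- function(g, path) {
  df <- data.frame(sample_id = rownames(g), g, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the sample table
#'
#' Tab-separated with a header; required columns `sample_id`, `status`,
#' `age`, `sex`, `environment`; optional `subpopulation`. Unknown columns are
#' kept but flagged with a warning.
#'
#' @param path TSV path.
#' @return `data.frame`, one row per sample.
#' @export
readSamples <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "status", "age", "sex", "environment")
  missing <- setdiff(required, colnames(df))
  if (length(missing))
    stop("sample table is missing required column(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(colnames(df), c(required, "subpopulation", "pc1", "pc2"))
  if (length(extra))
    warning("ignoring unknown sample table column(s): ",
            paste(extra, collapse = ", "))
  if (!all(df$status %in% c(0, 1)))
    stop("'status' must be 0 (unaffected) or 1 (affected)")
  if (!all(df$sex %in% c(0, 1))) stop("'sex' must be coded 0/1")
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id")
  df$status <- as.integer(df$status)
  df
}

#' Read variant annotation and derive SNP sets
#'
#' Columns `variant_id`, `gene`, `functional_class` (values `synonymous` /
#' `nonsynonymous`); optional `chrom`, `pos`. Each variant must belong to
#' exactly one gene. SNP sets are the per-gene variant lists in file order.
#'
#' @param path TSV path.
#' @return `list(variants = data.frame, sets = named list of variant ids)`.
#' @export
readAnnotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0)
    return(list(variants = df, sets = list()))
  required <- c("variant_id", "gene", "functional_class")
  missing <- setdiff(required, colnames(df))
  if (length(missing))
    stop("annotation is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (!all(df$functional_class %in% c("synonymous", "nonsynonymous")))
    stop("functional_class must be 'synonymous' or 'nonsynonymous'")
  if (anyDuplicated(df$variant_id)) {
    dup <- df$variant_id[duplicated(df$variant_id)][1]
    stop("variant listed more than once (multiple genes?): ", dup)
  }
  sets <- split(df$variant_id, factor(df$gene, levels = unique(df$gene)))
  list(variants = df, sets = sets)
}

#' Assemble a SnpSetExperiment from the tabular files
#'
#' @param genoPath,samplePath,annPath paths to the genotype, sample and
#'   annotation tables.
#' @param format genotype format, `"tsv"` or `"vcf"`.
#' @return a [SnpSetExperiment-class] with `maf` and `frequency_class` filled.
#' @export
readSnpSetExperiment <- function(genoPath, samplePath, annPath,
                                 format = c("tsv", "vcf")) {
  g <- readGenotypes(genoPath, match.arg(format))
  samples <- readSamples(samplePath)
  ann <- readAnnotations(annPath)
  x <- SnpSetExperiment(g, variants = ann$variants, samples = samples)
  classifyVariantFrequency(computeMaf(x))
}
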