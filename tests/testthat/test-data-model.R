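test_that("tabular genotype dialect round-trips exactly and validates entries", {
  set.seed(1)
  g <- randomGeno(7, 4)
  g[2, 3] <- NA
  path <- withr::local_tempfile(fileext = ".tsv")
  writeGenotypes(g, path)
  g2 <- readGenotypes(path, "tsv")
  expect_identical(g2, g)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tv1", "s1\t3"), bad)
  expect_error(readGenotypes(bad, "tsv"), "0, 1, 2")
})

test_that("VCF genotypes are coded as minor-allele counts regardless of REF/ALT", {
  vcfPath <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\trs2\tA\tG\t.\tPASS\t.\tGT\t1/1\t1|1\t0/1",
    "1\t300\trs3\tA\tG\t.\tPASS\t.\tGT\t./.\t0/0\t0/1"), vcfPath)
  g <- readGenotypes(vcfPath, "vcf")
  expect_equal(unname(g[, "rs1"]), c(0L, 1L, 2L))      # ALT is minor
  # rs2: ALT frequency 5/6 -> counts refer to REF (the minor allele)
  expect_equal(unname(g[, "rs2"]), c(0L, 0L, 1L))
  expect_equal(unname(g[, "rs3"]), c(NA_integer_, 0L, 1L))
})

test_that("VCF reader rejects non-diploid genotypes by variant name", {
  vcfPath <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "1\t100\trsX\tA\tG\t.\tPASS\t.\tGT\t0/1/1"), vcfPath)
  expect_error(readGenotypes(vcfPath, "vcf"), "rsX")
})

test_that("sample table reader validates and tolerates extras", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(sample_id = paste0("s", 1:4), status = c(1, 0, 0, 1),
                   age = c(40, 50, 60, 45), sex = c(0, 1, 0, 1),
                   environment = c(1, 0, 1, 0), shoe_size = 7:10)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(tab <- readSamples(path), "shoe_size")
  expect_equal(sum(tab$status == 1), 2)

  df$status <- NULL
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(suppressWarnings(readSamples(path)), "status")
})

test_that("annotation reader builds SNP sets in file order and rejects multi-gene variants", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(variant_id = paste0("v", 1:5),
                   gene = c("B", "B", "A", "B", "A"),
                   functional_class = c("synonymous", "nonsynonymous",
                                        "synonymous", "nonsynonymous",
                                        "nonsynonymous"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- readAnnotations(path)
  expect_equal(names(ann$sets), c("B", "A"))
  expect_equal(ann$sets$B, c("v1", "v2", "v4"))

  df$variant_id[2] <- "v1"; df$gene[2] <- "A"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readAnnotations(path), "v1")

  writeLines("variant_id\tgene\tfunctional_class", path)
  empty <- readAnnotations(path)
  expect_length(empty$sets, 0)
})

test_that("MAF is fold-corrected, order-invariant, and errors on all-missing variants", {
  g <- cbind(a = c(0L, 0L, 1L, 2L), b = c(0L, 0L, 0L, 0L),
             c = c(2L, 2L, 2L, 1L))
  rownames(g) <- paste0("s", 1:4)
  maf <- computeMaf(g)
  expect_equal(unname(maf), c(3 / 8, 0, 1 / 8))
  expect_true(all(maf >= 0 & maf <= 0.5))
  expect_equal(unname(computeMaf(g[c(3, 1, 4, 2), ])), unname(maf))

  g[, "a"] <- NA_integer_
  expect_error(computeMaf(g), "a")
})

test_that("frequency classification uses a strict 1% boundary", {
  expect_equal(classifyVariantFrequency(c(0.005, 0.05, 0.01, 0.0099)),
               c("rare", "common", "common", "rare"))
})

test_that("singleton and monomorphic variants are removed; 2-carrier variants kept", {
  g <- cbind(mono = rep(0L, 6), single = c(2L, 0L, 0L, 0L, 0L, 0L),
             dbl = c(1L, 1L, 0L, 0L, 0L, 0L))
  rownames(g) <- paste0("s", 1:6)
  fs <- filterSingletonVariants(g)
  expect_equal(colnames(fs$genotypes), "dbl")
  expect_setequal(fs$removed, c("mono", "single"))
})

test_that("monomorphic variants leave downstream statistics unchanged", {
  set.seed(5)
  g <- randomGeno(60, 3, maf = c(0.3, 0.2, 0.4))
  y <- rbinom(60, 1, 0.4)
  gPlus <- cbind(g, mono = rep(0L, 60))
  # the score test prunes the degenerate column, so the result must agree
  r1 <- logisticScoreTest(y, matrix(1, 60), g)
  r2 <- logisticScoreTest(y, matrix(1, 60), gPlus)
  expect_equal(r2@statistic, r1@statistic, tolerance = 1e-10)
  expect_equal(r2@df, r1@df)
})

test_that("low-burden genes are removed at the 1% carrier fraction; common-only genes kept", {
  n <- 697
  g <- matrix(0L, n, 3,
              dimnames = list(sprintf("s%03d", 1:n), c("v1", "v2", "v3")))
  g[1:6, 1] <- 1L    # gene LO: 6/697 carriers < 1%
  g[1:7, 2] <- 1L    # gene HI: 7/697 carriers >= 1%
  g[, 3] <- rbinom(n, 2, 0.3)  # gene CO: common only
  variants <- data.frame(variant_id = c("v1", "v2", "v3"),
                         gene = c("LO", "HI", "CO"),
                         functional_class = "nonsynonymous")
  x <- SnpSetExperiment(g, variants = variants)
  x <- classifyVariantFrequency(computeMaf(x))
  fl <- filterLowBurdenGenes(x)
  expect_equal(fl$removed, "LO")
  expect_setequal(names(snpSets(fl$object)), c("HI", "CO"))
})

test_that("singleton-then-low-burden filtering is idempotent", {
  set.seed(9)
  x <- tinyExperiment(n = 150)
  pass1 <- filterLowBurdenGenes(filterSingletonVariants(x)$object)$object
  fs2 <- filterSingletonVariants(pass1)
  fl2 <- filterLowBurdenGenes(fs2$object)
  expect_length(fs2$removed, 0)
  expect_length(fl2$removed, 0)
})

test_that("population PCs separate planted clusters and match an eigen oracle", {
  set.seed(21)
  n <- 80; p <- 150
  pop <- rep(c(1, 2), each = n / 2)
  f1 <- runif(p, 0.05, 0.35); f2 <- pmin(0.95, f1 + 0.45)
  g <- matrix(0L, n, p, dimnames = list(paste0("s", 1:n), paste0("v", 1:p)))
  g[pop == 1, ] <- rbinom(n / 2 * p, 2, rep(f1, each = n / 2))
  g[pop == 2, ] <- rbinom(n / 2 * p, 2, rep(f2, each = n / 2))
  scores <- computePopulationPCs(g, mafMin = 0.05, k = 2)

  # oracle: eigendecomposition of the centered covariance
  m <- scale(g, scale = FALSE)
  eg <- eigen(tcrossprod(m), symmetric = TRUE)
  expect_equal(abs(cor(scores[, 1], eg$vectors[, 1])), 1, tolerance = 1e-8)

  # PC1 cleanly separates the two clusters (silhouette > 0.9)
  s1 <- scores[, 1]
  sil <- vapply(seq_len(n), function(i) {
    a <- mean(abs(s1[i] - s1[pop == pop[i] & seq_len(n) != i]))
    b <- mean(abs(s1[i] - s1[pop != pop[i]]))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.9)

  # orthogonality and variant-order invariance up to the sign rule
  expect_lt(abs(crossprod(scores[, 1], scores[, 2])), 1e-6)
  scores2 <- computePopulationPCs(g[, sample(p)], mafMin = 0.05, k = 2)
  expect_equal(scores2, scores, tolerance = 1e-6)
})

test_that("PCs of degenerate inputs are zero", {
  g <- matrix(1L, 10, 5, dimnames = list(paste0("s", 1:10), paste0("v", 1:5)))
  g[, ] <- rep(c(0L, 1L, 2L, 1L, 0L), each = 10)  # identical rows
  scores <- computePopulationPCs(g, mafMin = 0.05, k = 2)
  expect_true(all(abs(scores) < 1e-8))

  # rank-1 centered data: second PC vanishes
  v <- c(rep(0L, 5), rep(2L, 5))
  g2 <- cbind(v1 = v, v2 = v, v3 = v)
  rownames(g2) <- paste0("s", 1:10)
  s2 <- computePopulationPCs(g2, mafMin = 0.05, k = 2)
  expect_true(all(abs(s2[, 2]) < 1e-8))
})

test_that("standardizeColumns yields exact moments and flags constants", {
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  out <- standardizeColumns(m)
  expect_equal(unname(out[, "a"]), c(-1, 0, 1))
  expect_equal(unname(out[, "b"]), c(0, 0, 0))
  expect_equal(unname(attr(out, "constant")), c(FALSE, TRUE))

  set.seed(3)
  r <- standardizeColumns(matrix(rnorm(60), 12))
  expect_true(all(abs(colMeans(r)) < 1e-12))
  expect_true(all(abs(apply(r, 2, sd) - 1) < 1e-12))
})

test_that("SnpSetExperiment validity catches bad genotypes and duplicate ids", {
  g <- matrix(c(0L, 1L, 2L, 0L), 2, 2,
              dimnames = list(c("s1", "s2"), c("v1", "v2")))
  x <- SnpSetExperiment(g)
  expect_s4_class(x, "SnpSetExperiment")
  g2 <- g; g2[1, 1] <- 5L
  expect_error(SnpSetExperiment(g2), "0, 1 or 2")
  g3 <- g; rownames(g3) <- c("s1", "s1")
  expect_error(SnpSetExperiment(g3))
})
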