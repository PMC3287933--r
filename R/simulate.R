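#' Configuration for the synthetic exome-like case-control generator
#'
#' The generator emulates the structure of a mini-exome case-control study of
#' unrelated individuals: three continental subpopulations with divergent
#' common-variant frequencies (Balding-Nichols model), a MAF spectrum in
#' which about 74% of variants are rare (MAF < 1%), synonymous/nonsynonymous
#' labels, a binary environmental exposure (smoking), and a logistic disease
#' model with optional marginal, gene-environment and SNP-SNP interaction
#' effects, with the option of fixing the affected/unaffected totals.
#'
#' Defaults mirror that design: 697 samples, affected/unaffected fixed at
#' 209/488, rare fraction 0.74, rare MAFs log-uniform between `1/(2n)` and
#' 0.01, common MAFs log-uniform on `[0.01, 0.5]`, subpopulation divergence
#' `Fst = 0.05` for common variants (rare variants share one frequency),
#' about 8 variants per gene, 70% nonsynonymous, smoking prevalence 0.3,
#' age ~ Normal(50, 10), sex ~ Bernoulli(0.5).
#'
#' @param nSamples number of individuals.
#' @param nGenes number of genes (SNP sets).
#' @param meanVariantsPerGene mean of the (shifted Poisson) per-gene variant
#'   count, minimum 1.
#' @param subpopProportions named proportions of the subpopulations.
#' @param fst Balding-Nichols divergence of common-variant frequencies.
#' @param rareFraction probability a variant is rare.
#' @param nonsynFraction probability a variant is nonsynonymous.
#' @param envPrevalence exposure prevalence.
#' @param prevalence target disease prevalence (defaults to 209/697).
#' @param fixedTotals logical; condition each replicate on
#'   `round(n * prevalence)` affected individuals.
#' @param betaAge,betaSex,betaEnv covariate log-odds effects (age centered
#'   at 50).
#' @param causal named list of per-gene effect specs, each a list with any
#'   of `betaBurden` (log-odds per standardized rare nonsynonymous burden),
#'   `betaCommon` (log-odds per standardized common variant, applied to each
#'   common variant of the gene), `gammaGE` (log-odds of exposure x burden)
#'   and `etaInt` (log-odds on the product of the gene's first two
#'   standardized common variants).
#' @param ageMean,ageSd age distribution.
#' @return a list of class `"SimConfig"`.
#' @export
simConfig <- function(nSamples = 697, nGenes = 50, meanVariantsPerGene = 8,
                      subpopProportions = c(EUR = 0.33, ASN = 0.34, AFR = 0.33),
                      fst = 0.05, rareFraction = 0.74, nonsynFraction = 0.7,
                      envPrevalence = 0.3, prevalence = 209 / 697,
                      fixedTotals = TRUE,
                      betaAge = 0.01, betaSex = 0.25, betaEnv = 0.5,
                      causal = list(), ageMean = 50, ageSd = 10) {
  stopifnot(abs(sum(subpopProportions) - 1) < 1e-8,
            rareFraction >= 0, rareFraction <= 1,
            nonsynFraction >= 0, nonsynFraction <= 1,
            envPrevalence > 0, envPrevalence < 1,
            prevalence > 0, prevalence < 1)
  cfg <- as.list(environment())
  class(cfg) <- "SimConfig"
  cfg
}

.bnFreq <- function(base, fst) {
  # Balding-Nichols subpopulation frequency around a shared base frequency
  a <- base * (1 - fst) / fst
  b <- (1 - base) * (1 - fst) / fst
  pmin(pmax(stats::rbeta(length(base), a, b), 1e-6), 1 - 1e-6)
}

#' Simulate genotypes, annotation and SNP sets
#'
#' Draws per-variant base minor allele frequencies from the configured
#' spectrum, diverges the common-variant frequencies across subpopulations
#' under the Balding-Nichols model (rare variants share the base frequency),
#' and draws genotypes as Binomial(2, f). Variants are laid out on
#' chromosomes with increasing positions so the PCA spacing filter is
#' exercisable. Deterministic under `seed`.
#'
#' @param cfg a [simConfig()] object.
#' @param seed integer seed.
#' @return a [SnpSetExperiment-class] with `gene`, `functional_class`,
#'   `chrom`, `pos` variant metadata and a `subpopulation` sample column
#'   (`maf`/`frequency_class` unset until [computeMaf()] runs).
#' @export
simulateGenotypes <- function(cfg, seed = 1) {
  set.seed(seed)
  n <- cfg$nSamples
  if (1 / (2 * n) >= 0.01)
    stop("sample size too small for the requested rare MAF floor")
  nv <- pmax(1L, stats::rpois(cfg$nGenes, cfg$meanVariantsPerGene - 1) + 1L)
  p <- sum(nv)
  gene <- rep(sprintf("G%03d", seq_len(cfg$nGenes)), nv)
  variantId <- sprintf("V%05d", seq_len(p))
  rare <- stats::runif(p) < cfg$rareFraction
  logU <- function(m, lo, hi) exp(stats::runif(m, log(lo), log(hi)))
  baseF <- numeric(p)
  baseF[rare] <- logU(sum(rare), 1 / (2 * n), 0.0099)
  baseF[!rare] <- logU(sum(!rare), 0.01, 0.5)
  fclass <- ifelse(stats::runif(p) < cfg$nonsynFraction,
                   "nonsynonymous", "synonymous")

  pops <- names(cfg$subpopProportions)
  popOf <- sample(rep(pops, times = round(cfg$subpopProportions * n))[seq_len(n)])
  if (length(popOf) < n)
    popOf <- c(popOf, sample(pops, n - length(popOf), replace = TRUE))

  freqs <- matrix(rep(baseF, each = length(pops)), nrow = length(pops),
                  dimnames = list(pops, variantId))
  for (popIdx in seq_along(pops))
    freqs[popIdx, !rare] <- .bnFreq(baseF[!rare], cfg$fst)

  g <- matrix(0L, n, p, dimnames = list(sprintf("S%04d", seq_len(n)), variantId))
  for (pop in pops) {
    idx <- which(popOf == pop)
    g[idx, ] <- matrix(stats::rbinom(length(idx) * p, 2L,
                                     rep(freqs[pop, ], each = length(idx))),
                       length(idx), p)
  }
  # orient to minor-allele counts (Balding-Nichols draws can push f past 0.5)
  f <- colSums(g) / (2 * n)
  flip <- f > 0.5
  g[, flip] <- 2L - g[, flip]

  geneRank <- match(gene, unique(gene))
  chrom <- ((geneRank - 1) %% 22) + 1
  pos <- integer(p)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    localGene <- match(geneRank[idx], unique(geneRank[idx]))
    within <- stats::ave(seq_along(idx), geneRank[idx], FUN = seq_along)
    pos[idx] <- localGene * 1000000L + within * 1500L
  }
  variants <- data.frame(variant_id = variantId, gene = gene,
                         functional_class = fclass, chrom = chrom, pos = pos,
                         stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = rownames(g), subpopulation = popOf,
                        stringsAsFactors = FALSE)
  SnpSetExperiment(g, variants = variants, samples = samples)
}

.causalPredictor <- function(x, cfg) {
  # genetic part of the linear predictor from the causal effect settings;
  # burden terms are returned separately (they multiply the exposure)
  g <- genoMatrix(x)
  rd <- SummarizedExperiment::rowData(x)
  maf <- computeMaf(g)
  eta <- numeric(nrow(g))
  geTerms <- list()
  truth <- list()
  std <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
  for (gn in names(cfg$causal)) {
    eff <- cfg$causal[[gn]]
    ids <- rownames(x)[as.character(rd$gene) == gn]
    if (!length(ids)) stop("causal gene not present in SNP sets: ", gn)
    rareNon <- ids[maf[ids] < 0.01 & rd[ids, "functional_class"] == "nonsynonymous"]
    common <- ids[maf[ids] >= 0.01]
    burden <- if (length(rareNon))
      std(rowSums(g[, rareNon, drop = FALSE])) else numeric(nrow(g))
    bb <- eff$betaBurden %||% 0
    bc <- eff$betaCommon %||% 0
    gg <- eff$gammaGE %||% 0
    ei <- eff$etaInt %||% 0
    if (bb != 0) eta <- eta + bb * burden
    if (bc != 0 && length(common))
      eta <- eta + rowSums(apply(g[, common, drop = FALSE], 2, std)) * bc
    if (ei != 0 && length(common) >= 2)
      eta <- eta + ei * std(g[, common[1]]) * std(g[, common[2]])
    if (gg != 0) geTerms[[gn]] <- gg * burden
    truth[[gn]] <- list(betaBurden = bb, betaCommon = bc, gammaGE = gg,
                        etaInt = ei)
  }
  list(eta = eta, geTerms = geTerms, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate phenotype, environment and covariates
#'
#' Draws smoking exposure, age and sex, builds the logistic linear predictor
#' from the covariate effects and the causal-gene settings (marginal burden and
#' common-variant effects, exposure x burden interactions, SNP-SNP
#' interaction products), calibrates the intercept so the expected disease
#' prevalence hits the target, and draws disease status. When
#' `cfg$fixedTotals` the status vector is redrawn until the affected total
#' equals `round(n * prevalence)` (rejection sampling), emulating a design
#' with fixed case/control totals.
#'
#' @param x a [SnpSetExperiment-class] from [simulateGenotypes()].
#' @param cfg the [simConfig()] used.
#' @param seed integer seed.
#' @param covariates optional data.frame with fixed `age` and `sex` columns
#'   (held constant across replicates of one genotype set).
#' @param maxAttempts rejection-sampling cap for fixed totals.
#' @return the object with `status`, `age`, `sex`, `environment` sample
#'   columns filled and the truth record in `metadata(x)$truth`.
#' @export
simulatePhenotypes <- function(x, cfg, seed = 1, covariates = NULL,
                               maxAttempts = 5000) {
  set.seed(seed)
  n <- ncol(x)
  if (is.null(covariates)) {
    age <- stats::rnorm(n, cfg$ageMean, cfg$ageSd)
    sex <- stats::rbinom(n, 1, 0.5)
  } else {
    age <- covariates$age; sex <- covariates$sex
  }
  env <- stats::rbinom(n, 1, cfg$envPrevalence)
  cp <- .causalPredictor(x, cfg)
  etaFixed <- cfg$betaAge * (age - cfg$ageMean) + cfg$betaSex * sex +
    cfg$betaEnv * env + cp$eta
  for (geb in cp$geTerms) etaFixed <- etaFixed + env * geb
  b0 <- stats::uniroot(function(b) mean(stats::plogis(b + etaFixed)) - cfg$prevalence,
                       c(-25, 25))$root
  pr <- stats::plogis(b0 + etaFixed)
  if (cfg$fixedTotals) {
    target <- round(n * cfg$prevalence)
    y <- NULL
    for (attempt in seq_len(maxAttempts)) {
      cand <- stats::rbinom(n, 1, pr)
      if (sum(cand) == target) { y <- cand; break }
    }
    if (is.null(y))
      stop("could not realize the fixed affected total after ", maxAttempts,
           " attempts")
  } else {
    y <- stats::rbinom(n, 1, pr)
  }
  cd <- SummarizedExperiment::colData(x)
  cd$status <- as.integer(y); cd$age <- age; cd$sex <- sex
  cd$environment <- env
  SummarizedExperiment::colData(x) <- cd
  S4Vectors::metadata(x)$truth <- cp$truth
  x
}

#' Generate paired screening/testing replicates
#'
#' Genotypes, age and sex are generated once and held fixed across every
#' replicate (as in a design where only phenotype and exposure are
#' re-simulated); each pair consists of two replicates with independently
#' drawn exposure and disease status. Per-replicate seeds are derived
#' deterministically from the master seed. MAF, frequency class and the two
#' population-structure PCs are precomputed on the shared genotypes.
#'
#' @param cfg a [simConfig()].
#' @param nPairs number of screening/testing pairs.
#' @param seed master seed.
#' @return list of `list(screen = , test = )` pairs of
#'   [SnpSetExperiment-class] objects.
#' @export
generateReplicates <- function(cfg, nPairs, seed = 1) {
  base <- simulateGenotypes(cfg, seed = seed)
  base <- classifyVariantFrequency(computeMaf(base))
  base <- computePopulationPCs(base)
  set.seed(seed + 1L)
  covariates <- data.frame(age = stats::rnorm(ncol(base), cfg$ageMean, cfg$ageSd),
                           sex = stats::rbinom(ncol(base), 1, 0.5))
  lapply(seq_len(nPairs), function(i) {
    s1 <- (seed * 131 + 2L * i) %% .Machine$integer.max
    s2 <- (seed * 131 + 2L * i + 1L) %% .Machine$integer.max
    list(screen = simulatePhenotypes(base, cfg, seed = s1, covariates = covariates),
         test = simulatePhenotypes(base, cfg, seed = s2, covariates = covariates))
  })
}

#' Write a simulated replicate to the tabular dialects
#'
#' Emits `genotypes.tsv`, `samples.tsv`, `annotation.tsv` and, when a truth
#' record is present, `truth.tsv` into `dir`.
#'
#' @param x a [SnpSetExperiment-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeReplicate <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGenotypes(genoMatrix(x), file.path(dir, "genotypes.tsv"))
  utils::write.table(sampleInfo(x), file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  vi <- variantInfo(x)
  utils::write.table(vi[, intersect(c("variant_id", "gene", "functional_class",
                                      "chrom", "pos"), colnames(vi))],
                     file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- S4Vectors::metadata(x)$truth
  if (!is.null(truth) && length(truth)) {
    rows <- do.call(rbind, lapply(names(truth), function(gn)
      data.frame(gene = gn, effect = names(unlist(truth[[gn]])),
                 coefficient = unlist(truth[[gn]]), stringsAsFactors = FALSE)))
    utils::write.table(rows, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
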