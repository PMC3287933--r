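# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately written from first principles, not by
# calling the functions under test.

# Bernoulli log-likelihood of a logistic model, for finite-difference oracles
logitLoglik <- function(theta, y, M) {
  eta <- drop(M %*% theta)
  sum(y * eta - log1p(exp(eta)))
}

# Richardson-extrapolated central-difference gradient and Hessian
fdGrad <- function(f, x, h = 1e-4) {
  g1 <- vapply(seq_along(x), function(j) {
    e <- x * 0; e[j] <- h; (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
  g2 <- vapply(seq_along(x), function(j) {
    e <- x * 0; e[j] <- h / 2; (f(x + e) - f(x - e)) / h
  }, numeric(1))
  (4 * g2 - g1) / 3
}

fdHessian <- function(f, x, h = 1e-3) {
  hess <- function(h) {
    d <- length(x)
    H <- matrix(0, d, d)
    for (i in seq_len(d)) for (j in i:d) {
      ei <- x * 0; ei[i] <- h
      ej <- x * 0; ej[j] <- h
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h^2)
    }
    H
  }
  (16 * hess(h / 2) - hess(h)) / 15
}

# Pearson chi-square of a 2x2 table, closed form N(ad-bc)^2/(r1 r2 c1 c2)
pearsonX2 <- function(tab) {
  N <- sum(tab)
  N * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    prod(rowSums(tab)) / prod(colSums(tab))
}

# Holm step-down, executed literally from its definition
holmOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, min(1, (m - i + 1) * p[o[i]]))
    adj[o[i]] <- running
  }
  adj
}

# random samples x variants genotype matrix with dimnames
randomGeno <- function(n, p, maf = runif(p, 0.05, 0.5)) {
  g <- matrix(rbinom(n * p, 2L, rep(maf, each = n)), n, p,
              dimnames = list(sprintf("s%03d", seq_len(n)),
                              sprintf("v%03d", seq_len(p))))
  g
}

# small two-gene experiment with both frequency classes and full sample data
tinyExperiment <- function(n = 120, seed = 11) {
  set.seed(seed)
  mafs <- c(0.003, 0.004, 0.006, 0.25, 0.40,   # gene A: 3 rare, 2 common
            0.002, 0.005, 0.30)                # gene B: 2 rare, 1 common
  g <- randomGeno(n, length(mafs), mafs)
  variants <- data.frame(
    variant_id = colnames(g),
    gene = rep(c("GA", "GB"), c(5, 3)),
    functional_class = c("synonymous", "nonsynonymous", "nonsynonymous",
                         "nonsynonymous", "synonymous",
                         "nonsynonymous", "synonymous", "nonsynonymous"),
    stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = rownames(g),
    status = rep(c(1L, 0L), length.out = n),
    age = rnorm(n, 50, 10),
    sex = rbinom(n, 1, 0.5),
    environment = rbinom(n, 1, 0.4),
    subpopulation = sample(c("EUR", "ASN", "AFR"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  x <- SnpSetExperiment(g, variants = variants, samples = samples)
  x <- classifyVariantFrequency(computeMaf(x))
  SummarizedExperiment::colData(x)$pc1 <- rnorm(n, sd = 0.1)
  SummarizedExperiment::colData(x)$pc2 <- rnorm(n, sd = 0.1)
  x
}

# null covariates + phenotype for calibration/power experiments
simCovariatePhenotype <- function(n, geneticEta = 0) {
  age <- rnorm(n, 50, 10)
  sex <- rbinom(n, 1, 0.5)
  env <- rbinom(n, 1, 0.3)
  eta <- -0.9 + 0.01 * (age - 50) + 0.25 * sex + 0.5 * env + geneticEta
  list(X = cbind(1, age - 50, sex, env), env = env,
       y = rbinom(n, 1, plogis(eta)))
}

# rare + common variant design used by the kernel experiments
simKernelDesign <- function(n, nRare = 15, nCommon = 5) {
  mafR <- exp(runif(nRare, log(0.002), log(0.01)))
  mafC <- runif(nCommon, 0.05, 0.5)
  cbind(matrix(rbinom(n * nRare, 2, rep(mafR, each = n)), n),
        matrix(rbinom(n * nCommon, 2, rep(mafC, each = n)), n))
}
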