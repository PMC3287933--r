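#' Logistic score test for joint genetic and gene-environment effects
#'
#' Fits the null logistic model of `y` on the covariates `X` alone and tests
#' `H0: a = b = 0` in
#' `logit P(y = 1) = X beta + Z a + (s * Z) b`,
#' where `s * Z` is the columnwise product of the environment exposure with
#' the genetic matrix. The statistic is the efficient score
#' `U' I_eff^{-1} U`, with `U` the score of the tested block at the null
#' maximum likelihood estimate and `I_eff` the tested-block information minus
#' the cross-information projected through the nuisance block (Schur
#' complement). Constant or collinear tested columns (in the null-weighted
#' metric) are dropped with a note; the reference distribution is chi-square
#' with the retained column count as degrees of freedom.
#'
#' @param y binary response (0/1).
#' @param X covariate matrix including an intercept column.
#' @param Z genetic matrix (raw genotypes or collapsed scores), one column
#'   minimum.
#' @param s optional environment vector; when supplied the interaction block
#'   `s * Z` is tested jointly with `Z`.
#' @return a [TestResult-class].
#' @export
logisticScoreTest <- function(y, X, Z, s = NULL) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(Z) == n)
  G <- Z
  if (!is.null(s)) {
    stopifnot(length(s) == n)
    G <- cbind(Z, Z * s)
  }
  colnames(G) <- paste0("g", seq_len(ncol(G)))

  nf <- fitNullLogistic(y, X)
  mu <- nf@fitted
  w <- nf@weights

  # prune tested columns that are degenerate in the weighted metric
  sw <- sqrt(w)
  qrAll <- qr(cbind(X * sw, G * sw))
  rank0 <- qr(X * sw)$rank
  keepIdx <- qrAll$pivot[seq_len(qrAll$rank)]
  keep <- sort(keepIdx[keepIdx > ncol(X)] - ncol(X))
  dropped <- setdiff(seq_len(ncol(G)), keep)
  if (!length(keep)) stop("no testable genetic signal: all tested columns degenerate")
  G <- G[, keep, drop = FALSE]

  U <- crossprod(G, y - mu)
  Xw <- X * w
  IXX <- crossprod(X, Xw)
  IXG <- crossprod(Xw, G)
  IGG <- crossprod(G * w, G)
  Ieff <- IGG - crossprod(IXG, solve(IXX, IXG))
  stat <- drop(crossprod(U, solve(Ieff, U)))
  df <- ncol(G)
  notes <- if (length(dropped))
    paste0("dropped ", length(dropped), " degenerate tested column(s)") else character()
  .TestResult("logistic_score", statistic = stat, df = df,
              pValue = stats::pchisq(stat, df, lower.tail = FALSE),
              pSource = "analytic", nUsed = n, notes = notes)
}

#' Hotelling T-squared test for a multivariate mean difference
#'
#' `T2 = (nA nB / (nA + nB)) d' S+ d` with `d` the mean difference and `S`
#' the pooled covariance. When `S` is full rank an exact F p-value is
#' attached; otherwise the Moore-Penrose pseudoinverse is used, the result
#' is flagged rank-deficient and only the statistic is returned (within the
#' screening pipeline p-values come from permutation regardless).
#'
#' @param A,B numeric matrices (observations in rows) or vectors for d = 1.
#' @return a [TestResult-class].
#' @export
.hotellingCore <- function(A, B) {
  nA <- nrow(A); nB <- nrow(B); d <- ncol(A)
  stopifnot(d == ncol(B), nA >= 1, nB >= 1)
  diff <- colMeans(A) - colMeans(B)
  df2 <- nA + nB - 2
  S <- matrix(0, d, d)
  if (nA > 1) S <- S + (nA - 1) * stats::cov(A)
  if (nB > 1) S <- S + (nB - 1) * stats::cov(B)
  if (df2 > 0) S <- S / df2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  tol <- max(ev, 0) * d * .Machine$double.eps * 1e3
  fullRank <- df2 >= d && all(ev > max(tol, 1e-300))
  Sinv <- if (fullRank) solve(S) else MASS::ginv(S)
  list(stat = drop(nA * nB / (nA + nB) * crossprod(diff, Sinv %*% diff)),
       fullRank = fullRank, nA = nA, nB = nB, d = d)
}

# bare statistic for permutation loops (no S4 result object)
.hotellingStat <- function(A, B) .hotellingCore(A, B)$stat

hotellingT2 <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  core <- .hotellingCore(A, B)
  nA <- core$nA; nB <- core$nB; d <- core$d
  df2 <- nA + nB - 2
  fullRank <- core$fullRank
  stat <- core$stat
  notes <- character()
  p <- NA_real_
  df <- NA_real_
  if (fullRank && nA + nB - d - 1 > 0) {
    fstat <- stat * (nA + nB - d - 1) / (d * df2)
    p <- stats::pf(fstat, d, nA + nB - d - 1, lower.tail = FALSE)
    df <- d
  } else {
    notes <- "rank-deficient, permutation p only"
  }
  .TestResult("hotelling_t2", statistic = stat, df = df, pValue = p,
              pSource = "analytic", nUsed = nA + nB, notes = notes)
}

#' Fisher-z test for differential gene-environment correlation
#'
#' Tests `H0: Corr(G, E | Y = 0) = Corr(G, E | Y = 1)` via the difference of
#' Fisher z-transformed within-group Pearson correlations,
#' `z = (atanh(rA) - atanh(rU)) / sqrt(1/(nA - 3) + 1/(nU - 3))`,
#' with a two-sided normal p-value. Within the screening pipeline the
#' absolute statistic is fed to the permutation engine instead.
#'
#' @param gscore per-sample genetic score (e.g. a collapsed score).
#' @param env per-sample exposure.
#' @param status binary phenotype.
#' @return a [TestResult-class].
#' @export
.geZCore <- function(gscore, env, status) {
  aff <- status == 1; unaff <- status == 0
  nA <- sum(aff); nU <- sum(unaff)
  if (nA < 4 || nU < 4) stop("each status group needs at least 4 samples")
  for (grp in list(gscore[aff], gscore[unaff], env[aff], env[unaff]))
    if (stats::sd(grp) == 0) stop("constant score or exposure within a group")
  rA <- stats::cor(gscore[aff], env[aff])
  rU <- stats::cor(gscore[unaff], env[unaff])
  if (abs(rA) >= 1 || abs(rU) >= 1) stop("degenerate correlation")
  list(z = (atanh(rA) - atanh(rU)) / sqrt(1 / (nA - 3) + 1 / (nU - 3)),
       rA = rA, rU = rU, nA = nA, nU = nU)
}

# bare statistic for permutation loops
.geZStat <- function(gscore, env, status) .geZCore(gscore, env, status)$z

geCorrelationTest <- function(gscore, env, status) {
  core <- .geZCore(gscore, env, status)
  z <- core$z; rA <- core$rA; rU <- core$rU; nA <- core$nA; nU <- core$nU
  .TestResult("ge_correlation", statistic = z,
              pValue = 2 * stats::pnorm(-abs(z)), pSource = "analytic",
              nUsed = nA + nU,
              notes = sprintf("rA=%.4f rU=%.4f", rA, rU))
}

#' Permutation p-value by resampling disease status
#'
#' Permutes the status labels only -- genotypes, covariates and exposure stay
#' fixed -- which preserves the affected/unaffected totals by construction.
#' `stat_fn` must return a statistic for which larger values are more
#' extreme (pass absolute values for two-sided tests). The p-value uses the
#' add-one convention `p = (1 + #{stat_b >= stat_obs}) / (B + 1)`, counting
#' ties as extreme. A permutation on which `stat_fn` fails is redrawn, at
#' most 10 times.
#'
#' @param statFn function of a status vector returning the statistic.
#' @param status observed binary status vector.
#' @param B number of permutations (>= 1).
#' @param seed optional integer seed for reproducibility.
#' @return a [TestResult-class] with `pSource = "permutation"`.
#' @export
permutationPvalue <- function(statFn, status, B, seed = NULL) {
  stopifnot(B >= 1)
  if (!is.null(seed)) set.seed(seed)
  obs <- statFn(status)
  if (!is.finite(obs)) stop("statistic not finite on the observed data")
  hits <- 0L
  for (b in seq_len(B)) {
    val <- NA_real_
    for (attempt in 1:10) {
      perm <- sample(status)
      val <- tryCatch(statFn(perm), error = function(e) NA_real_)
      if (is.finite(val)) break
    }
    if (!is.finite(val))
      stop("statistic failed on 10 consecutive permutations")
    if (val >= obs) hits <- hits + 1L
  }
  .TestResult("permutation", statistic = obs,
              pValue = (1 + hits) / (B + 1), pSource = "permutation",
              nUsed = length(status),
              notes = sprintf("B=%d", B))
}

#' Collect TestResult objects into a data.frame
#'
#' @param results named list of [TestResult-class] objects (names become the
#'   `gene` column).
#' @return data.frame with columns gene, method, statistic, df, p_value,
#'   p_source, n_used and the serialized moment parameters.
#' @export
resultsTable <- function(results) {
  do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    mom <- if (length(r@moments))
      paste(signif(r@moments, 8), collapse = ",") else NA_character_
    data.frame(gene = nm, method = r@method, statistic = r@statistic,
               df = r@df, p_value = r@pValue, p_source = r@pSource,
               n_used = r@nUsed, moments = mom, stringsAsFactors = FALSE)
  }))
}
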