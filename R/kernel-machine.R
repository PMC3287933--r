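#' Build a kernel matrix from a standardized design
#'
#' Linear kernel `K_ij = z_i' z_j`; quadratic kernel `K_ij = (1 + z_i' z_j)^2`,
#' a polynomial kernel that is positive semidefinite by construction and
#' whose feature space contains all pairwise products, so it models SNP-SNP
#' interactions. Columns of `Z` are expected to be standardized (see
#' [standardizeColumns()]); constant columns standardize to zero and simply
#' contribute nothing.
#'
#' @param Z samples x features matrix.
#' @param kernel `"linear"` or `"quadratic"`.
#' @return symmetric PSD kernel matrix, n x n.
#' @export
buildKernel <- function(Z, kernel = c("linear", "quadratic")) {
  kernel <- match.arg(kernel)
  Z <- as.matrix(Z)
  if (!all(is.finite(Z))) stop("non-finite entries in kernel input")
  G <- tcrossprod(Z)
  K <- if (kernel == "linear") G else (1 + G)^2
  (K + t(K)) / 2
}

#' Fit the null logistic model by iteratively reweighted least squares
#'
#' Standard GLM fit of `y` on `X` under the binomial family (via
#' `stats::glm.fit`), run to a relative deviance change below 1e-10 with at
#' most 100 iterations. Apparent separation (diverging coefficients or
#' fitted probabilities at the boundary) raises an error rather than
#' returning a silently divergent fit.
#'
#' @param y binary response.
#' @param X full-column-rank covariate matrix including an intercept.
#' @return a [NullFit-class].
#' @export
fitNullLogistic <- function(y, X) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  if (qr(X)$rank < ncol(X)) stop("covariate matrix is rank deficient")
  fit <- stats::glm.fit(X, y, family = stats::binomial(),
                        control = list(epsilon = 1e-10, maxit = 100))
  if (!fit$converged)
    stop("null logistic model did not converge after 100 iterations")
  if (max(abs(fit$coefficients)) > 30 ||
      any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10))
    stop("separation detected in the null model; consider a penalized fit")
  mu <- fit$fitted.values
  methods::new("NullFit", coef = fit$coefficients, fitted = mu,
               weights = mu * (1 - mu), X = X)
}

#' Variance-component score statistics and their null moments
#'
#' The score statistic for the absence of a kernel variance component is the
#' quadratic form `q = (y - mu)' K (y - mu) / 2` in the null residuals. Its
#' null mean and variance come from the efficient projected covariance: with
#' `D = diag(mu (1 - mu))` and `P0 = D - D X (X' D X)^{-1} X' D`,
#' `mean = tr(P0 K) / 2` and `variance = tr(P0 K P0 K) / 2`. The same is
#' computed for the gene-environment kernel `Ktilde` when supplied. Each
#' component is moment-matched to a scaled chi-square; a component whose
#' null variance is at machine zero is flagged degenerate.
#'
#' @param y binary response.
#' @param nullfit a [NullFit-class] from [fitNullLogistic()].
#' @param K main-effect kernel matrix (n x n).
#' @param Ktilde optional gene-environment kernel, built on the rows of the
#'   standardized design scaled by the exposure.
#' @return a [QComponents-class].
#' @export
varianceComponentScores <- function(y, nullfit, K, Ktilde = NULL) {
  mu <- nullfit@fitted
  w <- nullfit@weights
  X <- nullfit@X
  n <- length(y)
  stopifnot(nrow(K) == n, ncol(K) == n)
  r <- y - mu
  Xw <- X * w
  XtDX <- crossprod(X, Xw)
  if (rcond(XtDX) < 1e-14) stop("singular weighted information X'DX")

  componentMoments <- function(Kmat) {
    # P0 K = D K - D X (X'DX)^{-1} X' D K, formed without materializing P0
    P0K <- w * Kmat - Xw %*% solve(XtDX, crossprod(Xw, Kmat))
    c(mean = sum(diag(P0K)) / 2, variance = sum(P0K * t(P0K)) / 2)
  }

  qTau <- drop(crossprod(r, K %*% r)) / 2
  m1 <- componentMoments(K)
  qTilde <- NA_real_
  m2 <- c(mean = NA_real_, variance = NA_real_)
  if (!is.null(Ktilde)) {
    stopifnot(nrow(Ktilde) == n, ncol(Ktilde) == n)
    qTilde <- drop(crossprod(r, Ktilde %*% r)) / 2
    m2 <- componentMoments(Ktilde)
  }
  moments <- rbind(tau = m1, tauTilde = m2)
  degenerate <- c(is.na(m1["variance"]) || m1[["variance"]] < 1e-12,
                  is.na(m2["variance"]) || m2[["variance"]] < 1e-12)
  kappa <- nu <- rep(NA_real_, 2)
  for (j in 1:2) {
    if (!degenerate[j]) {
      mm <- momentMatchScaledChisq(moments[j, "mean"], moments[j, "variance"])
      kappa[j] <- mm[["kappa"]]; nu[j] <- mm[["nu"]]
    }
  }
  methods::new("QComponents", qTau = qTau, qTauTilde = qTilde,
               moments = moments, kappa = kappa, nu = nu,
               degenerate = degenerate, nUsed = as.integer(n))
}

#' Match a scaled chi-square distribution by its first two moments
#'
#' Finds `kappa` and `nu` such that a `kappa * chisq(nu)` variable has the
#' given mean and variance (Satterthwaite): `kappa = variance / (2 mean)`,
#' `nu = 2 mean^2 / variance`.
#'
#' @param mean,variance positive null moments of the quadratic form.
#' @return named numeric `c(kappa, nu)`.
#' @export
momentMatchScaledChisq <- function(mean, variance) {
  if (!is.finite(mean) || !is.finite(variance) || mean <= 0 || variance <= 0)
    stop("moment matching needs positive mean and variance")
  c(kappa = variance / (2 * mean), nu = 2 * mean^2 / variance)
}

#' Combined two-component kernel machine test
#'
#' Scales each non-degenerate component by its matched `kappa` and refers
#' the sum `Q = q_tau / kappa1 + q_tautilde / kappa2` to a chi-square with
#' `nu1 + nu2` degrees of freedom, treating the components as approximately
#' independent. A degenerate component contributes neither to `Q` nor to the
#' degrees of freedom.
#'
#' @param qc a [QComponents-class].
#' @return a [TestResult-class].
#' @export
combinedKernelTest <- function(qc) {
  qs <- c(qc@qTau, qc@qTauTilde)
  ok <- !qc@degenerate
  if (!any(ok)) stop("no variance components to test")
  Q <- sum(qs[ok] / qc@kappa[ok])
  df <- sum(qc@nu[ok])
  moments <- c(kappa1 = qc@kappa[1], nu1 = qc@nu[1],
               kappa2 = qc@kappa[2], nu2 = qc@nu[2])
  .TestResult("kernel_machine", statistic = Q, df = df, moments = moments,
              pValue = stats::pchisq(Q, df, lower.tail = FALSE),
              pSource = "analytic", nUsed = qc@nUsed,
              notes = if (any(qc@degenerate & c(TRUE, !is.null(qc@qTauTilde))))
                "degenerate component excluded" else character())
}

#' Logistic kernel machine variance-component test
#'
#' Convenience wrapper: standardizes the genetic design, builds the main
#' kernel (linear or quadratic) and, when an exposure is supplied, a linear
#' gene-environment kernel on the exposure-scaled rows, fits the null
#' logistic model on the covariates alone, and returns the combined
#' moment-matched test.
#'
#' @param y binary response.
#' @param X covariate matrix including the intercept (the exposure should be
#'   one of its columns).
#' @param Z genetic design: common-variant genotypes and/or collapsed
#'   rare-variant score columns (unstandardized; standardized internally).
#' @param s optional binary exposure driving the gene-environment component.
#' @param kernel main-effect kernel, `"linear"` or `"quadratic"`; the
#'   gene-environment kernel is always linear.
#' @return a [TestResult-class] with the method label recording the kernel.
#' @export
kernelMachineTest <- function(y, X, Z, s = NULL, kernel = c("linear", "quadratic")) {
  kernel <- match.arg(kernel)
  Zs <- standardizeColumns(as.matrix(Z))
  K <- buildKernel(Zs, kernel)
  Ktilde <- if (!is.null(s)) buildKernel(Zs * s, "linear") else NULL
  nf <- fitNullLogistic(y, X)
  qc <- varianceComponentScores(y, nf, K, Ktilde)
  res <- combinedKernelTest(qc)
  res@method <- paste0("kernel_machine_", kernel)
  res
}
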