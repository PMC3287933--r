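test_that("Madsen-Browning weights match the pseudocount formula", {
  # one variant, absent among 49 genotyped unaffected, 100 genotyped total
  g <- matrix(0L, 100, 1, dimnames = list(sprintf("s%03d", 1:100), "v1"))
  g[100, 1] <- 1L  # one affected carrier so the variant is not fully absent
  status <- rep(c(0L, 1L), c(49, 51))
  w <- madsenBrowningWeights(g, status)
  q <- (0 + 1) / (2 * 49 + 2)
  expect_equal(q, 0.01)
  expect_equal(unname(w), sqrt(100 * q * (1 - q)), tolerance = 1e-12)
  expect_equal(unname(w), 0.99499, tolerance = 1e-5)

  # variant absent in everyone still gets a finite positive weight
  g0 <- matrix(0L, 100, 1, dimnames = list(rownames(g), "v0"))
  expect_gt(unname(madsenBrowningWeights(g0, status)), 0)

  expect_error(madsenBrowningWeights(g, rep(1L, 100)), "unaffected")
})

test_that("doubling all counts scales the weight by about sqrt(2)", {
  mkW <- function(mU, nU, n) {
    status <- rep(c(1L, 0L), c(n - nU, nU))
    g <- matrix(0L, n, 1, dimnames = list(sprintf("s%04d", 1:n), "v"))
    g[which(status == 0)[seq_len(mU)], 1] <- 1L
    unname(madsenBrowningWeights(g, status))
  }
  w1 <- mkW(50, 490, 1000)
  w2 <- mkW(100, 980, 2000)
  expect_equal(w2 / w1, sqrt(2), tolerance = 0.02)
  # and q approaches the pseudocount-free limit m/(2n)
  q2 <- (100 + 1) / (2 * 980 + 2)
  expect_equal(q2, 100 / (2 * 980), tolerance = 0.01)
})

test_that("weighted-sum scores use inverse weights and ignore variant order", {
  x <- tinyExperiment()
  ws <- weightedSumScores(x, "GA")
  g <- genoMatrix(geneSubset(x, "GA"))
  rd <- SummarizedExperiment::rowData(geneSubset(x, "GA"))
  status <- sampleInfo(x)$status
  # brute-force recomputation per sample and class
  for (cls in c("synonymous", "nonsynonymous")) {
    ids <- rownames(geneSubset(x, "GA"))[rd$frequency_class == "rare" &
                                         rd$functional_class == cls]
    expected <- numeric(nrow(g))
    if (length(ids)) {
      w <- madsenBrowningWeights(g[, ids, drop = FALSE], status)
      for (i in seq_len(nrow(g)))
        expected[i] <- sum(g[i, ids] / w)
    }
    got <- if (cls == "synonymous") ws$wsSyn else ws$wsNonsyn
    expect_equal(unname(got), expected, tolerance = 1e-12)
  }
  # zero-genotype sample scores zero
  zeroRow <- which(rowSums(g) == 0)
  if (length(zeroRow))
    expect_equal(unname(ws$wsSyn[zeroRow[1]] + ws$wsNonsyn[zeroRow[1]]), 0)
})

test_that("the combined weighted sum is WS_syn + 2 WS_nonsyn, with errors on mismatch", {
  expect_equal(combinedWS(1.0, 0.5), 2.0)
  s <- c(0.2, 0.4); ns <- c(0, 0)
  expect_equal(combinedWS(s, ns), s)
  expect_equal(combinedWS(ns, s), 2 * s)
  expect_error(combinedWS(1:3, 1:2), "length")
})

test_that("common summary score contrasts case/control frequencies", {
  # one variant: m^A = 20 of n^A = 100, m^U = 10 of n^U = 100
  g <- matrix(0L, 200, 1, dimnames = list(sprintf("s%03d", 1:200), "v1"))
  status <- rep(c(1L, 0L), each = 100)
  g[1:10, 1] <- 2L            # 20 minor alleles among affected
  g[101:110, 1] <- 1L         # 10 among unaffected
  cs <- commonSummaryScore(g, status)
  expect_equal(unname(cs$coeffs), 0.10 - 0.05)
  expect_equal(unname(cs$score[1]), 0.1)   # I = 2 -> 2 * 0.05

  # swapping the labels negates coefficients and scores
  cs2 <- commonSummaryScore(g, 1L - status)
  expect_equal(cs2$coeffs, -cs$coeffs)
  expect_equal(cs2$score, -cs$score)

  # identical case/control frequencies -> all-zero scores
  gsym <- rbind(g[1:100, , drop = FALSE], g[1:100, , drop = FALSE])
  rownames(gsym) <- sprintf("t%03d", 1:200)
  expect_true(all(commonSummaryScore(gsym, status)$score == 0))

  expect_error(commonSummaryScore(g, rep(0L, 200)), "affected")
})

test_that("coefficient expectation vanishes under label permutation", {
  set.seed(77)
  check <- function(n) {
    g <- randomGeno(n, 3, maf = c(0.2, 0.3, 0.4))
    status <- rep(c(0L, 1L), length.out = n)
    cs <- replicate(1000, freqContrastCoeffs(g, sample(status)))
    rowMeans(cs)
  }
  m1 <- check(40)
  m2 <- check(160)
  expect_true(all(abs(m1) < 0.02))
  # mean |c_k| shrinks roughly as 1/sqrt(n)
  expect_lt(mean(abs(m2)), mean(abs(m1)))
})

test_that("collapsed scores satisfy the combination identity and order invariances", {
  set.seed(31)
  x <- tinyExperiment(n = 100)
  cs <- collapseGene(x, "GA")
  expect_equal(cs@wsCombined, cs@wsSyn + 2 * cs@wsNonsyn, tolerance = 1e-15)

  # sample order invariance: permute samples, scores permute accordingly
  perm <- sample(ncol(x))
  xp <- x[, perm]
  csp <- collapseGene(xp, "GA")
  expect_equal(csp@wsCombined, cs@wsCombined[perm], tolerance = 1e-12)
  expect_equal(csp@commonScore, cs@commonScore[perm], tolerance = 1e-12)

  # variant order invariance within the gene
  xv <- x[c(2, 1, 3:nrow(x)), ]
  csv <- collapseGene(xv, "GA")
  expect_equal(csv@wsCombined, cs@wsCombined, tolerance = 1e-12)
})

test_that("vectorized scores match a brute-force loop on random inputs", {
  set.seed(55)
  for (rep in 1:5) {
    g <- randomGeno(20, 15, maf = runif(15, 0.02, 0.45))
    status <- rbinom(20, 1, 0.5)
    if (!any(status == 0) || !any(status == 1)) next
    cf <- freqContrastCoeffs(g, status)
    sc <- commonSummaryScore(g, status)$score
    brute <- vapply(seq_len(20), function(i) sum(cf * g[i, ]), numeric(1))
    expect_equal(unname(sc), brute, tolerance = 1e-12)

    w <- madsenBrowningWeights(g, status)
    bruteW <- vapply(seq_len(15), function(k) {
      gU <- g[status == 0, k]
      q <- (sum(gU) + 1) / (2 * length(gU) + 2)
      sqrt(20 * q * (1 - q))
    }, numeric(1))
    expect_equal(unname(w), bruteW, tolerance = 1e-12)
  }
})
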