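# HLDA construction: state statistics, scatter matrices, eigenpair,
# projection.

test_that("state statistics use the two-point and n-1 formulas", {
  vals <- rbind(c(0, 0), c(2, 0), c(5, 5), c(7, 7))
  colnames(vals) <- c("d_1_3", "d_2_4")
  dm <- DescriptorMatrix(vals, parsePairLabels(colnames(vals)),
                         state = c("folded", "folded", "unfolded", "unfolded"))
  st <- suppressWarnings(stateStatistics(dm))  # 2 frames/state: expected
  expect_equal(unname(st$folded@mu), c(1, 0))
  expect_equal(unname(st$folded@sigma), matrix(c(2, 0, 0, 0), 2))
  expect_equal(st$folded@n, 2L)
})

test_that("excluded frames are ignored and degenerate states regularized", {
  set.seed(30)
  vals <- matrix(rnorm(16), 8, 2)
  colnames(vals) <- c("d_1_3", "d_2_4")
  st <- c("folded", "folded", "excluded", "excluded", rep("unfolded", 4))
  dm <- DescriptorMatrix(vals, parsePairLabels(colnames(vals)), state = st)
  expect_warning(s <- stateStatistics(dm), "rank-deficient")
  expect_equal(s$folded@n + s$unfolded@n, 6L)
  # identical frames: zero covariance, the ridge path still yields a model
  vals2 <- rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 2))
  colnames(vals2) <- c("d_1_3", "d_2_4")
  dm2 <- DescriptorMatrix(vals2, parsePairLabels(colnames(vals2)),
                          state = c("folded", "folded", "unfolded", "unfolded"))
  s2 <- suppressWarnings(stateStatistics(dm2))
  m <- solveHLDA(s2)
  expect_true(is.finite(hldaEigenvalue(m)))
})

test_that("sampled moments recover known Gaussian parameters", {
  set.seed(31)
  mu <- c(1, -2, 0.5)
  sig <- randomSPD(3)
  labels <- c("d_1_3", "d_1_4", "d_2_5")
  n <- 1e4
  v <- matrix(rnorm(n * 3), n, 3) %*% chol(sig) +
    matrix(mu, n, 3, byrow = TRUE)
  colnames(v) <- labels
  dm <- DescriptorMatrix(rbind(v, v[1:100, ]),
                         parsePairLabels(labels),
                         state = c(rep("folded", n), rep("unfolded", 100)))
  st <- stateStatistics(dm)
  expect_true(all(abs(st$folded@mu - mu) < 3 * sqrt(diag(sig) / n)))
  expect_lt(max(abs(st$folded@sigma - sig)), 6 * max(diag(sig)) / sqrt(n))
})

test_that("harmonic within-scatter matches hand and high-precision values", {
  expect_equal(harmonicWithinScatter(diag(2), diag(2)), 0.5 * diag(2))
  expect_equal(harmonicWithinScatter(matrix(1), matrix(3)), matrix(0.75))
  set.seed(32)
  for (i in 1:5) {
    sF <- randomSPD(4); sU <- randomSPD(4)
    # independent route: Cholesky-based inversion
    oracle <- chol2inv(chol(chol2inv(chol(sF)) + chol2inv(chol(sU))))
    expect_equal(harmonicWithinScatter(sF, sU), oracle, tolerance = 1e-10)
  }
})

test_that("between-scatter is the half outer product of the mean gap", {
  expect_equal(betweenScatter(c(1, 2), c(1, 2)), matrix(0, 2, 2))
  expect_equal(betweenScatter(0, 2), matrix(2))
  set.seed(33)
  a <- rnorm(5); b <- rnorm(5)
  sb <- betweenScatter(a, b)
  expect_equal(sum(diag(sb)), 0.5 * sum((a - b)^2))   # trace identity
  expect_lte(qr(sb)$rank, 1)
})

test_that("scalar and 2-D worked cases give the forced eigenpair", {
  # 1-D: muF = 0, muU = 2, SigmaF = SigmaU = 1 -> Sw = 0.5, lambda = 4
  m1 <- solveHLDA(statsPair(0, 2, matrix(1), matrix(1)))
  expect_equal(hldaEigenvalue(m1), 4)
  expect_equal(unname(cvWeights(m1)), 1)
  # 2-D worked case
  m2 <- solveHLDA(statsPair(c(0, 0), c(1, 1), diag(c(1, 4)), diag(c(2, 2))))
  expect_equal(hldaEigenvalue(m2), 1.125)
  expect_equal(unname(cvWeights(m2)), c(0.8944, 0.4472), tolerance = 1e-4)
  # coincident means: flagged, zero lambda
  expect_warning(m0 <- solveHLDA(statsPair(c(1, 1), c(1, 1), diag(2), diag(2))),
                 "no separation")
  expect_true(m0@noSeparation)
  expect_equal(hldaEigenvalue(m0), 0)
})

test_that("closed form agrees with a dense generalized eigensolver", {
  set.seed(34)
  for (i in 1:100) {
    p <- sample(2:10, 1)
    muF <- rnorm(p); muU <- rnorm(p)
    sF <- randomSPD(p); sU <- randomSPD(p)
    m <- solveHLDA(statsPair(muF, muU, sF, sU))
    ref <- eigenLambda(muF, muU, sF, sU)
    expect_equal(hldaEigenvalue(m), ref$lambda, tolerance = 1e-10)
    wRef <- ref$w / sqrt(sum(ref$w^2))
    expect_lt(min(sum((unname(cvWeights(m)) - wRef)^2),
                  sum((unname(cvWeights(m)) + wRef)^2)), 1e-16)
    # package eigen route agrees too
    mE <- solveHLDA(statsPair(muF, muU, sF, sU), method = "eigen")
    expect_equal(hldaEigenvalue(mE), hldaEigenvalue(m), tolerance = 1e-9)
  }
})

test_that("lambda is invariant under affine descriptor maps", {
  set.seed(35)
  p <- 5
  muF <- rnorm(p); muU <- rnorm(p)
  sF <- randomSPD(p); sU <- randomSPD(p)
  lam <- hldaEigenvalue(solveHLDA(statsPair(muF, muU, sF, sU)))
  for (i in 1:50) {
    A <- matrix(rnorm(p * p), p, p) + diag(p)
    while (abs(det(A)) < 1e-3) A <- matrix(rnorm(p * p), p, p) + diag(p)
    cshift <- rnorm(p)
    lamT <- hldaEigenvalue(solveHLDA(statsPair(
      drop(A %*% muF) + cshift, drop(A %*% muU) + cshift,
      A %*% sF %*% t(A), A %*% sU %*% t(A))))
    expect_equal(lamT, lam, tolerance = 1e-8)
  }
})

test_that("sampling recovers the true direction and eigenvalue", {
  set.seed(36)
  p <- 6
  muF <- rep(0, p)
  muU <- c(1, 0.5, 0, 0, -0.5, 0.2)
  sF <- randomSPD(p, 1); sU <- randomSPD(p, 1)
  ref <- eigenLambda(muF, muU, sF, sU)
  wTrue <- drop(solve(ref$sw, muF - muU)); wTrue <- wTrue / sqrt(sum(wTrue^2))
  dm <- gaussianDescriptors(muF, muU, sF, sU, nPerState = 1e4,
                            labels = sprintf("d_1_%d", 3:8))
  m <- fitHLDA(dm, prune = FALSE)
  expect_gt(abs(sum(unname(cvWeights(m)) * wTrue)), 0.99)
  expect_lt(abs(hldaEigenvalue(m) / ref$lambda - 1), 0.05)
})

test_that("lambda grows strictly with the mean gap at fixed covariances", {
  set.seed(37)
  sF <- randomSPD(4); sU <- randomSPD(4)
  dir <- rnorm(4); dir <- dir / sqrt(sum(dir^2))
  lam <- vapply(c(0.5, 1, 2, 4), function(g)
    hldaEigenvalue(solveHLDA(statsPair(rep(0, 4), g * dir, sF, sU))),
    numeric(1))
  expect_true(all(diff(lam) > 0))
})

test_that("projection is a labelled, linear dot product", {
  set.seed(38)
  dm <- gaussianDescriptors(c(0, 0), c(2, 1), diag(2), diag(2), 500,
                            labels = c("d_1_3", "d_2_4"))
  m <- fitHLDA(dm, prune = FALSE)
  s <- projectCV(dm, m)
  expect_equal(s, unname(drop(descriptorValues(dm) %*% cvWeights(m))))
  # W = e1 returns the first descriptor column
  m1 <- m
  m1@weights <- setNames(c(1, 0), pairLabels(m))
  expect_equal(projectCV(dm, m1), unname(descriptorValues(dm)[, 1]))
  # linearity: doubling the descriptor values doubles s
  dm2 <- DescriptorMatrix(2 * descriptorValues(dm),
                          parsePairLabels(pairLabels(dm)))
  expect_equal(projectCV(dm2, m), 2 * s)
  # column order does not matter: matched by label
  vperm <- descriptorValues(dm)[, c(2, 1)]
  dmP <- DescriptorMatrix(vperm, parsePairLabels(colnames(vperm)))
  expect_equal(projectCV(dmP, m), s)
  # missing descriptor is named
  dmM <- DescriptorMatrix(descriptorValues(dm)[, 1, drop = FALSE],
                          parsePairLabels("d_1_3"))
  expect_error(projectCV(dmM, m), "d_2_4")
})

test_that("1-D HLDA on the projected samples reproduces lambda", {
  set.seed(39)
  sig <- randomSPD(4, 1)  # equal state covariances: identity holds exactly
  muF <- rep(0, 4); muU <- c(1.5, -0.5, 1, 0.3)
  dm <- gaussianDescriptors(muF, muU, sig, sig, 2e4,
                            labels = sprintf("d_1_%d", 3:6))
  m <- fitHLDA(dm, prune = FALSE)
  s <- projectCV(dm, m)
  st <- frameStates(dm)
  lam1d <- 0.5 * (mean(s[st == "unfolded"]) - mean(s[st == "folded"]))^2 *
    (1 / var(s[st == "folded"]) + 1 / var(s[st == "unfolded"]))
  expect_lt(abs(lam1d / hldaEigenvalue(m) - 1), 0.05)
})
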