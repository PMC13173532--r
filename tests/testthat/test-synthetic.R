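# Synthetic two-state generator: Langevin double well, descriptor mapping,
# mutants, biased escapes, toy coordinates.

test_that("high barrier confines a short run to its starting well", {
  spec <- twoStateSpec(barrierHeight = 20)
  tr <- simulateDoubleWell(spec, nSteps = 1e4, seed = 1)
  expect_true(all(latentX(tr) < 0))
})

test_that("within-well variance matches the Boltzmann quadrature oracle", {
  spec <- twoStateSpec(barrierHeight = 4, wellSeparation = 1)
  tr <- simulateDoubleWell(spec, nSteps = 4e5, x0 = 1, seed = 2)
  x <- latentX(tr)
  xw <- x[x > 0]
  # oracle: numeric quadrature of the Boltzmann law restricted to x > 0
  U <- function(x) 4 * ((x / 1)^2 - 1)^2
  Z <- integrate(function(x) exp(-U(x)), 0, Inf)$value
  m1 <- integrate(function(x) x * exp(-U(x)), 0, Inf)$value / Z
  m2 <- integrate(function(x) x^2 * exp(-U(x)), 0, Inf)$value / Z
  varOracle <- m2 - m1^2
  expect_lt(abs(var(xw) / varOracle - 1), 0.15)
  # the harmonic approximation kT a^2 / (8 dU) is only reliable for stiff
  # wells; check its 20% band in that regime
  spec10 <- twoStateSpec(barrierHeight = 10)
  x10 <- latentX(simulateDoubleWell(spec10, 4e5, x0 = 1, seed = 20))
  expect_lt(abs(var(x10[x10 > 0]) / (1 / 80) - 1), 0.20)
})

test_that("trajectories are bitwise reproducible given (spec, seed)", {
  spec <- twoStateSpec()
  t1 <- simulateDoubleWell(spec, 3000, seed = 42)
  t2 <- simulateDoubleWell(spec, 3000, seed = 42)
  expect_identical(latentX(t1), latentX(t2))
  expect_false(identical(latentX(t1),
                         latentX(simulateDoubleWell(spec, 3000, seed = 43))))
})

test_that("unstable or ill-posed time steps are refused by name", {
  spec <- twoStateSpec(barrierHeight = 10)
  expect_error(simulateDoubleWell(spec, 100, dt = 1, seed = 1), "dt")
})

test_that("long-run latent histogram matches the Boltzmann law (chi-squared)", {
  spec <- twoStateSpec(barrierHeight = 3)
  tr <- simulateDoubleWell(spec, nSteps = 2e6, seed = 3, recordStride = 20L)
  x <- latentX(tr)
  U <- function(x) 3 * (x^2 - 1)^2
  br <- seq(-1.6, 1.6, length.out = 25)
  xin <- x[x > br[1] & x < br[25]]
  ct <- tabulate(findInterval(xin, br, all.inside = TRUE), nbins = 24)
  pb <- vapply(seq_len(24), function(i)
    integrate(function(z) exp(-U(z)), br[i], br[i + 1])$value, numeric(1))
  pb <- pb / sum(pb)
  # effective sample size: the recorded frames are still autocorrelated, so
  # rescale counts by an ESS estimated from the lag-1 autocorrelation
  rho1 <- cor(xin[-1], xin[-length(xin)])
  ess <- length(xin) * (1 - rho1) / (1 + rho1)
  chi2 <- sum((ct / length(xin) - pb)^2 / pb) * ess
  expect_lt(chi2, qchisq(0.999, df = 23))
})

test_that("brute-force MFPT increases strictly with barrier height", {
  m <- vapply(c(3, 4, 5, 6), function(dU) {
    f <- bruteForceFPT(twoStateSpec(barrierHeight = dU), nEvents = 100,
                       seed = dU)
    mean(f)
  }, numeric(1))
  expect_true(all(diff(m) > 0))
})

test_that("descriptor mapping follows the generative formula", {
  pairs <- pairTable(4, 1)
  spec <- twoStateSpec(nResidues = 4, minSeparation = 1,
                       loadings = c(1, rep(0, 5)), offsets = 0, noiseSD = 0)
  tr <- simulateDoubleWell(spec, 500, seed = 5)
  dm <- mapToDescriptors(tr, spec, seed = 6)
  v <- descriptorValues(dm)
  expect_equal(unname(v[, 1]), latentX(tr))  # noiseless identity loading
  expect_true(all(v[, -1] == 0))
  # b = 0 everywhere: no signal, downstream lambda ~ 0 relative to signal case
  spec0 <- twoStateSpec(loadings = 0, noiseSD = 0.2)
  dm0 <- basinDescriptors(spec0, 2000, seed = 7)
  m0 <- fitHLDA(dm0, prune = FALSE)
  spec1 <- twoStateSpec()
  m1 <- fitHLDA(basinDescriptors(spec1, 2000, seed = 7), prune = FALSE)
  expect_lt(hldaEigenvalue(m0), 0.01 * hldaEigenvalue(m1))
})

test_that("per-well descriptor means match the law of large numbers", {
  spec <- twoStateSpec(barrierHeight = 12)  # high barrier: clean wells
  n <- 1e4
  for (sgn in c(-1, 1)) {
    tr <- simulateDoubleWell(spec, n - 1, x0 = sgn * 1, seed = 8 + sgn)
    dm <- mapToDescriptors(tr, spec, seed = 10 + sgn)
    mu <- colMeans(descriptorValues(dm))
    muExp <- spec@offsets + spec@loadings * sgn * spec@wellSeparation
    # 3 sigma / sqrt(n) band, inflated for latent-mean wobble around +/- a
    tol <- 3 * sqrt(spec@noiseSD^2 + spec@loadings^2 * var(latentX(tr))) /
      sqrt(n) + abs(spec@loadings) * abs(mean(latentX(tr)) - sgn * 1)
    expect_true(all(abs(mu - muExp) <= tol + 3e-3))
  }
})

test_that("makeMutant applies deltas, preserves the input, and validates", {
  spec <- twoStateSpec()
  mut <- makeMutant(spec, list(wellSeparation = 0.5))
  expect_equal(mut@wellSeparation, 1.5)
  expect_equal(spec@wellSeparation, 1)          # original untouched
  expect_equal(mut@barrierHeight, spec@barrierHeight)
  expect_equal(makeMutant(spec, list()), spec)  # identity
  expect_error(makeMutant(spec, list(barrierHeight = -10)), "non-positive")
  expect_error(makeMutant(spec, list(bogus = 1)), "unknown")
})

test_that("lambda is strictly increasing in well separation (closed form)", {
  spec <- twoStateSpec()
  lam <- vapply(c(0.8, 1.0, 1.2, 1.4, 1.6), function(a) {
    m <- makeMutant(spec, list(wellSeparation = a - spec@wellSeparation))
    # rank-1 closed form: lambda = 1/2 dmu' Sw^-1 dmu with dmu = 2 a b and
    # equal state covariances Sigma = var(x) b b' + diag(sigma^2)
    vx <- m@kT * m@wellSeparation^2 / (8 * m@barrierHeight * m@kT)
    sig <- vx * tcrossprod(m@loadings) + diag(m@noiseSD^2)
    sw <- solve(solve(sig) + solve(sig))
    dmu <- 2 * m@wellSeparation * m@loadings
    0.5 * drop(t(dmu) %*% solve(sw, dmu))
  }, numeric(1))
  expect_true(all(diff(lam) > 0))
})

test_that("zero-hill biased run reproduces the unbiased dynamics", {
  spec <- twoStateSpec()
  w <- rep(1 / 6, 36)
  tr <- simulateDoubleWell(spec, 3000, seed = 42)
  run <- runBiasedEscape(spec, w, hillHeight = 0, stopThreshold = 99,
                         maxSteps = 3000, seed = 42)
  expect_identical(latentX(run), latentX(tr))
  expect_false(run@crossed)
  expect_equal(accelFactor(run), 1)
})

test_that("acceleration factor is always >= 1 and hills follow the pace", {
  spec <- twoStateSpec()
  w <- rep(1 / 6, 36)
  for (seed in 1:5) {
    run <- runBiasedEscape(spec, w, seed = seed)
    expect_gte(accelFactor(run), 1)
    expect_true(all(biasEnergy(run) >= 0))
    if (nrow(run@hills) > 1)
      expect_equal(unique(diff(run@hills$time)), 1)  # pace = 1 per unit time
  }
})

test_that("biased escape requires unit-norm CV weights", {
  spec <- twoStateSpec()
  expect_error(runBiasedEscape(spec, rep(1, 36), seed = 1), "unit-norm")
})

test_that("toy coordinates follow their occupancy and jitter level", {
  f <- refHelix(); u <- refExtended()
  # zero jitter, all folded: RMSD 0 to the folded reference
  fr <- generateToyCoordinates(f, u, rep("folded", 4), 0, seed = 1)
  expect_equal(max(rmsdSeries(fr, f)), 0, tolerance = 1e-12)
  # zero jitter, alternating: RMSD alternates between 0 and RMSD(f, u)
  fr2 <- generateToyCoordinates(f, u, c("folded", "unfolded", "folded",
                                        "unfolded"), 0, seed = 1)
  r <- rmsdSeries(fr2, f)
  expect_equal(r[c(1, 3)], c(0, 0), tolerance = 1e-12)
  expect_equal(r[c(2, 4)], rep(kabschRMSD(u, f), 2), tolerance = 1e-12)
  expect_error(generateToyCoordinates(f, u[1:5, ], rep("folded", 2), 0, 1),
               "atom count")
  expect_error(generateToyCoordinates(f, u, c("folded", "melted"), 0, 1),
               "occupancy")
})

test_that("jittered frames match an independent per-frame Kabsch oracle", {
  f <- refHelix()
  fr <- generateToyCoordinates(f, refExtended(), rep("folded", 50), 0.05,
                               seed = 9)
  r <- rmsdSeries(fr, f)
  # oracle: direct numeric minimization over rotations per frame
  oracle <- vapply(seq_len(50), function(i) numericRMSD(fr[i, , ], f),
                   numeric(1))
  expect_equal(r, oracle, tolerance = 1e-6)
})
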