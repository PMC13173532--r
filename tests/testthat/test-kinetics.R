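# Kinetic inference: rescaling, survival fitting, exponentiality tests,
# FES, Marcus barriers, scans and correlations.

test_that("time rescaling reproduces closed-form acceleration factors", {
  # zero bias: t* = tau, alpha = 1
  r0 <- rescaleFPT(rep(0, 100), dt = 0.1, biasedFPT = 10)
  expect_equal(r0@rescaledFPT, 10)
  expect_equal(accelFactor(r0), 1)
  # constant V = kT ln 2 doubles the clock exactly
  r2 <- rescaleFPT(rep(log(2), 80), dt = 0.25, biasedFPT = 20)
  expect_equal(r2@rescaledFPT, 40, tolerance = 1e-12)
  # piecewise V: 0 on the first half, kT ln 3 on the second
  tau <- 10; dt <- 0.01; n <- tau / dt
  V <- c(rep(0, n / 2), rep(log(3), n / 2))
  rp <- rescaleFPT(V, dt, tau)
  expect_equal(rp@rescaledFPT, tau / 2 + 3 * tau / 2, tolerance = 1e-12)
  expect_error(rescaleFPT(c(0.1, -0.2), 1, 2), "negative")
  expect_error(rescaleFPT(rep(0, 3), 1, 10), "cover")
})

test_that("survival fitting recovers an exponential rate", {
  set.seed(51)
  t <- rexp(200, rate = 0.1)
  est <- fitMFPT(t)
  # censored-MLE oracle at the same cutoff: the two estimators agree
  ts <- sort(t); m <- est@mSelected
  kOracle <- m / (sum(ts[1:m]) + (200 - m) * ts[m])
  expect_equal(est@kMLE, kOracle)
  expect_lt(abs(rateConstant(est) / kOracle - 1), 0.15)
  expect_gt(est@r2, 0.95)
  # accuracy against the true MFPT, median over independent draws
  errs <- vapply(1:11, function(s) {
    set.seed(400 + s)
    abs(mfpt(fitMFPT(rexp(200, 0.1))) / 10 - 1)
  }, numeric(1))
  expect_lt(median(errs), 0.15)
  # degenerate inputs are refused
  expect_error(fitMFPT(rexp(5, 1)), "too few")
  expect_error(fitMFPT(rep(2, 50)), "identical")
})

test_that("the estimate is exactly equivariant under time rescaling", {
  set.seed(52)
  t <- rexp(150, 0.2)
  e1 <- fitMFPT(t)
  e3 <- fitMFPT(t * 7)
  expect_equal(mfpt(e3), 7 * mfpt(e1), tolerance = 1e-9)
  expect_equal(e3@mSelected, e1@mSelected)
})

test_that("right-censored records enter through the survival denominator", {
  set.seed(53)
  t <- sort(rexp(100, 0.5))
  rec <- data.frame(rescaledFPT = c(t[1:80], rep(NA, 20)),
                    crossed = rep(c(TRUE, FALSE), c(80, 20)))
  est <- fitMFPT(rec)
  expect_equal(est@nTotal, 100L)
  expect_equal(est@nCrossed, 80L)
  # dropping the censored runs instead biases the rate upward
  estDrop <- fitMFPT(t[1:80])
  expect_gt(rateConstant(estDrop), rateConstant(est))
})

test_that("the fastest-1/8 protocol fixes the cutoff", {
  set.seed(54)
  t <- rexp(200, 0.1)
  est <- fitMFPT(t, fraction = 1 / 8)
  expect_equal(est@mSelected, 25L)
  expect_equal(nrow(est@scan), 1L)
  # on exponential data the survival fit and the censored MLE at the same
  # cutoff estimate the same rate
  expect_lt(abs(rateConstant(est) / est@kMLE - 1), 0.4)
  expect_true(is.finite(mfpt(est)) && mfpt(est) > 0)
})

test_that("exponential samples pass and uniform samples fail the tests", {
  set.seed(55)
  passKS <- passLil <- failUnif <- 0
  for (s in 1:20) {
    t <- rexp(200, 0.3)
    et <- exponentialityTests(t, kHat = 1 / mean(t), nBoot = 300, seed = s)
    passKS <- passKS + (et$ks.p > 0.2)
    passLil <- passLil + (et$lilliefors.p > 0.05)
    u <- runif(200)
    eu <- exponentialityTests(u, nBoot = 300, seed = s)
    failUnif <- failUnif + (eu$lilliefors.p < 0.05)
  }
  expect_gte(passKS, 16)     # >= 80%
  expect_gte(passLil, 16)
  expect_gte(failUnif, 19)   # >= 95%
})

test_that("exponentiality tests handle boundaries and guard nBoot", {
  et <- exponentialityTests(rexp(5, 1), nBoot = 100, seed = 1)
  expect_true(et$ks.p >= 0 && et$ks.p <= 1)
  expect_true(et$lilliefors.p >= 0 && et$lilliefors.p <= 1)
  expect_error(exponentialityTests(rexp(4, 1)), "at least 5")
  expect_error(exponentialityTests(rexp(50, 1), nBoot = 50), "nBoot")
})

test_that("FES estimation inverts known sample distributions", {
  set.seed(56)
  # uniform samples: flat profile within Monte-Carlo error
  u <- runif(2e4)
  fes <- estimateFES(u, bins = 20)
  ok <- !is.na(fes$F)
  sigma <- sqrt(1 / (2e4 / 20))  # ~ relative count error per bin
  expect_lt(max(fes$F[ok]), 3 * sigma * 2)
  # standard Gaussian: F(s) = s^2/2 + const, curvature within 10%
  g <- rnorm(5e4)
  fes2 <- estimateFES(g, bins = 40)
  sel <- !is.na(fes2$F) & abs(fes2$s) < 2
  fit <- lm(F ~ I(s^2 / 2), data = fes2[sel, ], weights = fes2$count[sel])
  expect_lt(abs(coef(fit)[2] - 1), 0.1)
  # doubling kT doubles F pointwise
  fesA <- estimateFES(g, kT = 1, bins = 30)
  fesB <- estimateFES(g, kT = 2, bins = 30)
  expect_equal(fesB$F, 2 * fesA$F)
  expect_error(estimateFES(g, bins = 1), "bins")
  expect_warning(estimateFES(rnorm(50), bins = 30), "noisy")
})

test_that("two-component CV samples give a two-minimum FES with growing barrier", {
  set.seed(57)
  barrier <- vapply(c(2, 3.5), function(gap) {
    s <- c(rnorm(2e4, -gap / 2, 0.5), rnorm(2e4, gap / 2, 0.5))
    fes <- estimateFES(s, bins = 60)
    mid <- abs(fes$s) < gap / 4
    min(fes$F[mid], na.rm = TRUE)
  }, numeric(1))
  expect_gt(barrier[2], barrier[1])
})

test_that("Marcus barrier matches hand values and grows with separation", {
  expect_equal(marcusBarrier(parabolicBasins(-1, 1)), 0.5)
  expect_equal(marcusBarrier(parabolicBasins(-2, 2)), 2.0)
  # general case against numeric root-finding on the quadratic
  b <- parabolicBasins(sF = 0, sU = 2, kappaF = 2, kappaU = 1, deltaF = 0.3)
  f <- function(s) 0.5 * 2 * s^2 - (0.3 + 0.5 * (s - 2)^2)
  sX <- uniroot(f, c(1e-9, 2 - 1e-9), tol = 1e-12)$root
  expect_equal(marcusBarrier(b), 0.5 * 2 * (sX - 0)^2, tolerance = 1e-9)
  # monotone in separation at fixed curvature and offset
  seps <- seq(1, 3, 0.5)
  dF <- vapply(seps, function(a)
    marcusBarrier(parabolicBasins(-a / 2, a / 2, 1.3, 0.8, 0.2)), numeric(1))
  expect_true(all(diff(dF) > 0))
  # non-crossing configuration is an error
  expect_error(marcusBarrier(parabolicBasins(0, 1, 1, 1, deltaF = 10)),
               "cross")
})

test_that("correlation helper reproduces textbook formulas", {
  x <- c(1, 2, 3, 5, 8, 9, 12)
  y <- 2 * x + 1
  cm <- correlateMetric(x, y)
  expect_equal(cm$pearson.r, 1)
  expect_equal(cm$spearman.rho, 1)
  # monotone nonlinear: rho stays 1, |r| < 1
  cm2 <- correlateMetric(x, exp(x))
  expect_equal(cm2$spearman.rho, 1)
  expect_lt(abs(cm2$pearson.r), 1)
  # fixed 7-point vectors vs direct formula evaluation
  set.seed(58)
  a <- rnorm(7); b <- rnorm(7)
  cm3 <- correlateMetric(a, b)
  rHand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  tStat <- rHand * sqrt(5 / (1 - rHand^2))
  expect_equal(cm3$pearson.r, rHand)
  expect_equal(cm3$pearson.p, 2 * pt(-abs(tStat), df = 5))
  expect_equal(cm3$spearman.rho, cor(rank(a), rank(b)))
  # degenerate input is flagged, not an error
  expect_false(correlateMetric(rep(1, 5), rnorm(5))$defined)
  expect_error(correlateMetric(1:2, 1:2), ">= 3")
})

test_that("threshold scan is consistent with a direct correlate call", {
  set.seed(59)
  # three synthetic systems with known rates; unbiased series
  mkRuns <- function(rate, n = 40) lapply(seq_len(n), function(i) {
    fpt <- rexp(1, rate)
    list(series = c(rep(0, round(fpt / 0.1)), 1), dt = 0.1)
  })
  systems <- list(A = mkRuns(1), B = mkRuns(0.5), C = mkRuns(0.25))
  metric <- c(A = 1, B = 2, C = 3)
  scan <- thresholdScan(systems, grid = 0.5, metric, reference = "A",
                        mMin = 10)
  expect_equal(nrow(scan), 1)
  m <- attr(scan, "mfpt")[1, ]
  direct <- correlateMetric(metric, log(m / m[["A"]]))
  expect_equal(scan$spearman.rho, direct$spearman.rho)
  expect_equal(scan$pearson.r, direct$pearson.r)
  expect_equal(scan$spearman.rho, 1)
  # identical metric: undefined correlations flagged as NA
  scan2 <- thresholdScan(systems, grid = 0.5, c(A = 1, B = 1, C = 1),
                         reference = "A")
  expect_true(is.na(scan2$pearson.r))
  # unreachable threshold: all cells missing
  scan3 <- thresholdScan(systems, grid = 5, metric, reference = "A")
  expect_equal(scan3$nMissing, 3)
  expect_true(is.na(scan3$spearman.rho))
})
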