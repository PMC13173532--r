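## Kinetic inference from bias-accelerated trajectories: acceleration-
## factor time rescaling, progressive exponential survival fitting with
## max-R^2 cutoff selection, KS/Lilliefors exponentiality validation,
## free-energy profiles from histograms, Marcus-parabola barriers,
## threshold scans and metric-vs-MFPT correlation.

#' Rescale a biased first-passage time to physical time
#'
#' \eqn{t^* = \sum_{t < \tau} \Delta t\, e^{V(t)/kT}} (left Riemann sum of
#' the instantaneous acceleration over the biased trajectory up to the
#' crossing), with acceleration factor \eqn{\alpha = t^*/\tau \ge 1}.
#'
#' @param biasEnergy per-frame bias energy \eqn{V(t)} in kT units,
#'   frame 0 at time 0; must be non-negative and cover
#'   \eqn{[0, \tau]}.
#' @param dt time per frame (> 0).
#' @param biasedFPT the biased first-passage time \eqn{\tau}.
#' @return an [FPTRecord-class].
#' @examples
#' rescaleFPT(rep(log(2), 100), dt = 0.1, biasedFPT = 10)  # t* = 2 tau
#' @export
rescaleFPT <- function(biasEnergy, dt, biasedFPT) {
  stopifnot(dt > 0, biasedFPT >= 0)
  if (any(biasEnergy < 0))
    stop("negative bias energy entries: the bias is non-negative by construction")
  nsteg <- round(biasedFPT / dt)
  if (abs(nsteg * dt - biasedFPT) > 1e-6 * max(dt, biasedFPT))
    stop("biasedFPT is not a multiple of dt")
  if (length(biasEnergy) < nsteg)
    stop("bias energy series does not cover [0, biasedFPT]")
  tstar <- if (nsteg == 0) 0 else sum(dt * exp(biasEnergy[seq_len(nsteg)]))
  alpha <- if (biasedFPT > 0) tstar / biasedFPT else 1
  new("FPTRecord", biasedFPT = biasedFPT, accelFactor = alpha,
      rescaledFPT = tstar, crossed = TRUE)
}

#' Collect first-passage records from biased runs
#'
#' @param runs list of [BiasedRun-class] and/or [FPTRecord-class] objects.
#' @return data.frame with columns \code{biasedFPT}, \code{accelFactor},
#'   \code{rescaledFPT}, \code{crossed}.
#' @export
fptRecords <- function(runs) {
  rows <- lapply(runs, function(r) {
    if (is(r, "BiasedRun") || is(r, "FPTRecord"))
      data.frame(biasedFPT = r@biasedFPT, accelFactor = r@accelFactor,
                 rescaledFPT = r@rescaledFPT, crossed = r@crossed)
    else stop("runs must be BiasedRun or FPTRecord objects")
  })
  do.call(rbind, rows)
}

# normalize fitMFPT input to (rescaled times of crossed runs, nTotal)
.fptTimes <- function(records) {
  if (is.numeric(records))
    return(list(t = as.numeric(records), nTotal = length(records)))
  if (is.list(records) && !is.data.frame(records))
    records <- fptRecords(records)
  stopifnot(is.data.frame(records),
            all(c("rescaledFPT", "crossed") %in% names(records)))
  list(t = records$rescaledFPT[records$crossed],
       nTotal = nrow(records))
}

# scale-invariant 1-D least-squares fit of S(t) = exp(-k t) to points
# (t_i, S_i); optimized over u = k * mean(t) so the estimate is exactly
# equivariant under time rescaling
.fitExpSurvival <- function(t, S, scale = c("survival", "log-survival", "cdf")) {
  scale <- match.arg(scale)
  tm <- mean(t)
  if (scale == "log-survival") {
    keep <- S > 0
    k <- -sum(t[keep] * log(S[keep])) / sum(t[keep]^2)
    pred <- -k * t[keep]
    obs <- log(S[keep])
    r2 <- 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
    return(list(k = k, r2 = r2))
  }
  obs <- if (scale == "cdf") 1 - S else S
  ss <- function(u) {
    pred <- exp(-u * t / tm)
    if (scale == "cdf") pred <- 1 - pred
    sum((pred - obs)^2)
  }
  # the objective is flat for k far above the data scale, so bracket the
  # minimum on a log-spaced grid before local refinement
  uGrid <- 10^seq(-6, 2.5, length.out = 140)
  i <- which.min(vapply(uGrid, ss, numeric(1)))
  lo <- uGrid[max(1L, i - 1L)]
  hi <- uGrid[min(length(uGrid), i + 1L)]
  opt <- optimize(ss, interval = c(lo, hi), tol = 1e-12)
  r2 <- 1 - opt$objective / sum((obs - mean(obs))^2)
  list(k = opt$minimum / tm, r2 = r2)
}

#' Estimate the escape rate and MFPT by progressive survival fitting
#'
#' For each cutoff \eqn{m} (from \code{mMin} up to the number of crossed
#' records) the empirical survival of the \eqn{m} fastest rescaled
#' first-passage times is fit to \eqn{S(t) = e^{-kt}}; uncrossed and
#' slower records enter through the denominator as right-censoring
#' (\eqn{S(t_{(i)}) = 1 - i/n_{total}}). The estimate with the highest
#' \eqn{R^2} is selected and the MFPT is \eqn{1/k}. The censored
#' maximum-likelihood rate
#' \eqn{\hat k = m / (\sum_{i \le m} t_{(i)} + (n - m)\, t_{(m)})} at the
#' selected cutoff is reported as a cross-check.
#'
#' @param records first-passage observations: a numeric vector of rescaled
#'   times (all crossed), a data.frame with columns \code{rescaledFPT} and
#'   \code{crossed}, or a list of [BiasedRun-class]/[FPTRecord-class].
#' @param mMin smallest cutoff considered (default 10).
#' @param fraction if given, skip the scan and fit the fastest
#'   \code{fraction} of all records (e.g. 1/8).
#' @param scale scale on which the fit residuals and \eqn{R^2} are
#'   computed: \code{"survival"} (default), \code{"log-survival"} or
#'   \code{"cdf"}.
#' @return an [MFPTEstimate-class].
#' @examples
#' set.seed(1)
#' mfpt(fitMFPT(rexp(200, rate = 0.1)))
#' @export
fitMFPT <- function(records, mMin = 10L, fraction = NULL,
                    scale = c("survival", "log-survival", "cdf")) {
  scale <- match.arg(scale)
  inp <- .fptTimes(records)
  t <- sort(inp$t)
  n <- inp$nTotal
  nc <- length(t)
  if (nc < mMin)
    stop("too few crossings (", nc, ") for mMin = ", mMin)
  if (length(unique(t)) == 1L)
    stop("degenerate ECDF: all first-passage times identical")
  ms <- if (!is.null(fraction)) {
    stopifnot(fraction > 0, fraction <= 1)
    m <- min(nc, max(2L, ceiling(fraction * n)))
    m
  } else seq.int(mMin, nc)
  scan <- lapply(ms, function(m) {
    ti <- t[seq_len(m)]
    S <- 1 - seq_len(m) / n
    fit <- .fitExpSurvival(ti, S, scale)
    data.frame(m = m, k = fit$k, r2 = fit$r2)
  })
  scan <- do.call(rbind, scan)
  best <- scan[which.max(scan$r2), ]
  m <- best$m
  kMLE <- m / (sum(t[seq_len(m)]) + (n - m) * t[m])
  new("MFPTEstimate", rate = best$k, mfpt = 1 / best$k, r2 = best$r2,
      mSelected = as.integer(m), kMLE = kMLE, nTotal = as.integer(n),
      nCrossed = as.integer(nc), scan = scan)
}

# KS statistic of a sample against Exp(rate)
.ksStatExp <- function(t, rate) {
  t <- sort(t)
  n <- length(t)
  Fi <- pexp(t, rate)
  max(max(seq_len(n) / n - Fi), max(Fi - (seq_len(n) - 1) / n))
}

#' Exponentiality tests for rescaled first-passage times
#'
#' Validates the Poisson escape assumption. The Kolmogorov-Smirnov test
#' compares the sample to Exp(\code{kHat}) with the supplied rate treated
#' as known. The Lilliefors variant re-estimates the rate from the sample
#' (and from every bootstrap replicate), with the p-value obtained by
#' seeded parametric bootstrap since the exponential-Lilliefors null has
#' no convenient closed form. The conventional acceptance criteria are
#' KS \eqn{p > 0.2} and Lilliefors \eqn{p > 0.05}.
#'
#' @param times rescaled first-passage times (\eqn{\ge 5} values).
#' @param kHat rate for the KS reference distribution; default: the
#'   sample-mean rate \eqn{1/\bar t}.
#' @param nBoot bootstrap replicates for the Lilliefors p (\eqn{\ge 100};
#'   default 1000).
#' @param seed integer seed for the bootstrap.
#' @return list with \code{ks.p}, \code{ks.stat}, \code{lilliefors.p},
#'   \code{lilliefors.stat}, and logical \code{pass} (KS at 0.2,
#'   Lilliefors at 0.05).
#' @export
exponentialityTests <- function(times, kHat = NULL, nBoot = 1000L, seed = 1L) {
  stopifnot(is.numeric(times), all(is.finite(times)), all(times >= 0))
  if (length(times) < 5L) stop("need at least 5 samples")
  if (nBoot < 100L) stop("nBoot < 100 gives unstable p-values")
  n <- length(times)
  if (is.null(kHat)) kHat <- 1 / mean(times)
  ks <- suppressWarnings(ks.test(times, "pexp", rate = kHat))
  dObs <- .ksStatExp(times, 1 / mean(times))
  dBoot <- .withSeed(seed, vapply(seq_len(nBoot), function(b) {
    tb <- rexp(n, 1)
    .ksStatExp(tb, 1 / mean(tb))   # rate re-estimated per replicate
  }, numeric(1)))
  lp <- (1 + sum(dBoot >= dObs)) / (nBoot + 1)
  list(ks.p = unname(ks$p.value), ks.stat = unname(ks$statistic),
       lilliefors.p = lp, lilliefors.stat = dObs,
       pass = c(ks = unname(ks$p.value) > 0.2, lilliefors = lp > 0.05))
}

#' Free-energy profile from CV samples
#'
#' Boltzmann inversion of a histogram:
#' \eqn{F(s) = -kT \log \hat p(s)}, shifted so the minimum is 0. Empty
#' bins are undefined (NA).
#'
#' @param samples CV samples.
#' @param kT thermal energy (default 1).
#' @param bins number of equal-width bins (\eqn{\ge 2}).
#' @return data.frame with bin centers \code{s}, free energy \code{F},
#'   and \code{count}.
#' @export
estimateFES <- function(samples, kT = 1, bins = 50L) {
  stopifnot(is.numeric(samples), all(is.finite(samples)))
  if (bins < 2L) stop("bins must be >= 2")
  if (length(samples) < 10L * bins)
    warning("fewer than 10 samples per bin on average; F(s) will be noisy")
  br <- seq(min(samples), max(samples), length.out = bins + 1L)
  ct <- tabulate(findInterval(samples, br, rightmost.closed = TRUE,
                              all.inside = TRUE), nbins = bins)
  dens <- ct / (length(samples) * diff(br))
  Fv <- ifelse(ct > 0, -kT * log(dens), NA_real_)
  Fv <- Fv - min(Fv, na.rm = TRUE)
  data.frame(s = (br[-1L] + br[-(bins + 1L)]) / 2, F = Fv, count = ct)
}

#' Barrier height from two parabolic basins (Marcus picture)
#'
#' Solves \eqn{\frac{1}{2}\kappa_F (s - s_F)^2 =
#' \Delta F + \frac{1}{2}\kappa_U (s - s_U)^2} for the crossing point
#' \eqn{s^\ddagger} strictly between the minima and returns
#' \eqn{\Delta F^\ddagger = \frac{1}{2}\kappa_F (s^\ddagger - s_F)^2}, the
#' free-energy difference between the folded minimum and the crossing.
#' Increasing the separation of the minima raises the crossing energy,
#' hence the barrier.
#'
#' @param basins a [ParabolicBasinPair-class].
#' @return the barrier height \eqn{\Delta F^\ddagger} (energy units).
#' @examples
#' b <- parabolicBasins(sF = -1, sU = 1, kappaF = 1, kappaU = 1, deltaF = 0)
#' marcusBarrier(b)  # 0.5
#' @export
marcusBarrier <- function(basins) {
  stopifnot(is(basins, "ParabolicBasinPair"))
  kF <- basins@kappaF; kU <- basins@kappaU
  sF <- basins@sF; sU <- basins@sU; dF <- basins@deltaF
  A <- 0.5 * (kF - kU)
  B <- kU * sU - kF * sF
  C <- 0.5 * kF * sF^2 - 0.5 * kU * sU^2 - dF
  lo <- min(sF, sU); hi <- max(sF, sU)
  roots <- if (abs(A) < 1e-12) {
    if (abs(B) < 1e-12) numeric(0) else -C / B
  } else {
    disc <- B^2 - 4 * A * C
    if (disc < 0) numeric(0)
    else (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  }
  roots <- roots[roots > lo & roots < hi]
  if (!length(roots))
    stop("parabolas do not cross strictly between the minima")
  # when both roots fall inside, the physical saddle is the lower crossing
  sX <- roots[which.min(0.5 * kF * (roots - sF)^2)]
  0.5 * kF * (sX - sF)^2
}

#' Construct a ParabolicBasinPair
#'
#' @param sF,sU basin minima positions (must differ).
#' @param kappaF,kappaU curvatures (> 0).
#' @param deltaF free-energy offset of the unfolded minimum.
#' @return a [ParabolicBasinPair-class].
#' @export
parabolicBasins <- function(sF, sU, kappaF = 1, kappaU = 1, deltaF = 0) {
  new("ParabolicBasinPair", sF = as.numeric(sF), sU = as.numeric(sU),
      kappaF = as.numeric(kappaF), kappaU = as.numeric(kappaU),
      deltaF = as.numeric(deltaF))
}

#' Correlate a per-system metric with kinetics
#'
#' Product-moment (Pearson, with two-sided p) and rank (Spearman)
#' correlation between a per-system metric (e.g. \eqn{\lambda} or
#' \eqn{I_r}) and per-system log MFPT ratios.
#'
#' @param x metric per system (\eqn{n \ge 3} finite values).
#' @param y log MFPT ratio per system (same length).
#' @return list with \code{pearson.r}, \code{pearson.p},
#'   \code{spearman.rho}, \code{n}, and \code{defined} (FALSE when either
#'   input has zero variance).
#' @export
correlateMetric <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need >= 3 systems with finite values")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(pearson.r = NA_real_, pearson.p = NA_real_,
                spearman.rho = NA_real_, n = length(x), defined = FALSE))
  ct <- cor.test(x, y)
  list(pearson.r = unname(ct$estimate), pearson.p = ct$p.value,
       spearman.rho = cor(x, y, method = "spearman"), n = length(x),
       defined = TRUE)
}

# normalize one run for thresholdScan: needs a progress series, a per-frame
# bias series in kT (optional) and the frame spacing
.scanRun <- function(run, dt) {
  if (is(run, "BiasedRun")) {
    tg <- timeGrid(run)
    list(series = latentX(run), bias = biasEnergy(run),
         dt = if (length(tg) > 1L) tg[2L] - tg[1L] else dt)
  } else if (is.list(run) && !is.null(run$series)) {
    list(series = run$series, bias = run$bias,
         dt = if (!is.null(run$dt)) run$dt else dt)
  } else if (is.numeric(run)) {
    list(series = run, bias = NULL, dt = dt)
  } else stop("runs must be BiasedRun objects, numeric series, or lists ",
              "with a 'series' element")
}

# FPT of one run at a threshold, bias-rescaled when a bias series exists
.scanFPT <- function(run, threshold) {
  idx <- which(run$series >= threshold)
  if (!length(idx)) {
    cens <- if (is.null(run$bias)) (length(run$series) - 1L) * run$dt
            else sum(run$dt * exp(run$bias[-length(run$bias)]))
    return(c(t = NA_real_, crossed = 0, censor = cens))
  }
  i <- idx[1L]
  tau <- (i - 1L) * run$dt
  tstar <- if (is.null(run$bias) || i == 1L) tau
           else sum(run$dt * exp(run$bias[seq_len(i - 1L)]))
  c(t = tstar, crossed = 1, censor = NA_real_)
}

#' Scan first-passage thresholds and correlate a metric with MFPT
#'
#' For each threshold in the grid, recomputes first-passage times of every
#' run (rescaling by the recorded bias where present), fits per-system
#' MFPTs by progressive survival fitting, and correlates the per-system
#' metric with the log MFPT ratio to the reference system. Cells where a
#' system has fewer crossings than \code{mMin} are marked missing.
#'
#' @param systems named list of systems; each system is a list of runs
#'   ([BiasedRun-class] objects, numeric progress series, or lists with
#'   elements \code{series}, optional \code{bias} in kT and \code{dt}).
#' @param grid numeric vector of first-passage thresholds.
#' @param metric named numeric vector, one metric value per system
#'   (\eqn{\lambda} or \eqn{I_r}).
#' @param reference name of the reference system for the MFPT ratio;
#'   default: the first system.
#' @param dt default frame spacing for runs that do not carry one.
#' @param mMin,fraction,scale passed to [fitMFPT()].
#' @return data.frame with one row per threshold: the correlations, the
#'   number of systems used and the number missing. The per-system MFPT
#'   table is attached as attribute \code{"mfpt"}.
#' @export
thresholdScan <- function(systems, grid, metric, reference = NULL, dt = 1,
                          mMin = 10L, fraction = NULL,
                          scale = "survival") {
  stopifnot(is.list(systems), !is.null(names(systems)),
            length(systems) >= 3L)
  stopifnot(all(names(systems) %in% names(metric) |
                  is.null(names(metric)) && length(metric) == length(systems)))
  if (is.null(names(metric))) names(metric) <- names(systems)
  if (is.null(reference)) reference <- names(systems)[1L]
  stopifnot(reference %in% names(systems))
  runs <- lapply(systems, function(sys) lapply(sys, .scanRun, dt = dt))
  mfptTab <- matrix(NA_real_, length(grid), length(systems),
                    dimnames = list(NULL, names(systems)))
  rows <- lapply(seq_along(grid), function(gi) {
    th <- grid[gi]
    est <- vapply(runs, function(sys) {
      f <- vapply(sys, .scanFPT, numeric(3), threshold = th)
      tcross <- f["t", f["crossed", ] == 1]
      if (length(tcross) < mMin || length(unique(tcross)) < 2L)
        return(NA_real_)
      rec <- data.frame(rescaledFPT = f["t", ], crossed = f["crossed", ] == 1)
      mfpt(fitMFPT(rec, mMin = mMin, fraction = fraction, scale = scale))
    }, numeric(1))
    mfptTab[gi, ] <<- est
    ok <- is.finite(est)
    y <- log(est / est[reference])
    res <- if (sum(ok) >= 3L && is.finite(est[reference])) {
      cm <- tryCatch(correlateMetric(metric[names(systems)][ok], y[ok]),
                     error = function(e) NULL)
      if (is.null(cm) || !cm$defined)
        list(pearson.r = NA_real_, pearson.p = NA_real_,
             spearman.rho = NA_real_)
      else cm
    } else list(pearson.r = NA_real_, pearson.p = NA_real_,
                spearman.rho = NA_real_)
    data.frame(threshold = th, pearson.r = res$pearson.r,
               pearson.p = res$pearson.p, spearman.rho = res$spearman.rho,
               nSystems = sum(ok), nMissing = sum(!ok))
  })
  out <- do.call(rbind, rows)
  attr(out, "mfpt") <- mfptTab
  out
}
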