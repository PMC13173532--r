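## Harmonic linear discriminant analysis: state statistics, scatter
## matrices, the leading eigenpair and CV projection.
##
## For two states the problem  max_W (W' Sb W)/(W' Sw W)  with
## Sb = (1/2) dmu dmu'  and  Sw = (SigmaF^-1 + SigmaU^-1)^-1  has the rank-1
## closed form  W ~ Sw^-1 dmu,  lambda = (1/2) dmu' Sw^-1 dmu.  The general
## eigensolver route is kept as a tested fallback.

#' Per-state descriptor statistics
#'
#' Sample mean and unbiased (n - 1) covariance of the descriptors within
#' each state-restricted ensemble. Excluded frames are ignored. A state
#' with fewer frames than descriptors + 1 yields a rank-deficient
#' covariance; a warning is emitted and downstream inversion relies on the
#' ridge regularization (see [harmonicWithinScatter()]).
#'
#' @param x a [DescriptorMatrix-class].
#' @param labels per-frame state labels: a [StateLabels-class], or a
#'   character/factor vector with entries folded/unfolded/excluded. Omit to
#'   use the states stored in \code{x}.
#' @return named list of [StateStats-class], elements \code{folded} and
#'   \code{unfolded}.
#' @export
stateStatistics <- function(x, labels = NULL) {
  stopifnot(is(x, "DescriptorMatrix"))
  lab <- if (is.null(labels)) frameStates(x)
         else if (is(labels, "StateLabels")) as.character(stateAssignments(labels))
         else as.character(labels)
  if (is.null(lab)) stop("no state labels stored in x and none supplied")
  if (length(lab) != ncol(x))
    stop("one label per frame required")
  v <- descriptorValues(x)
  out <- lapply(c("folded", "unfolded"), function(st) {
    vi <- v[lab == st, , drop = FALSE]
    if (nrow(vi) < 2L)
      stop("state '", st, "' has fewer than 2 frames")
    if (nrow(vi) < ncol(vi) + 1L)
      warning("state '", st, "' has fewer frames (", nrow(vi),
              ") than descriptors + 1 (", ncol(vi) + 1L,
              "); covariance is rank-deficient and will be ridge-regularized")
    new("StateStats", state = st, mu = colMeans(vi), sigma = cov(vi),
        n = nrow(vi), regularized = FALSE)
  })
  names(out) <- c("folded", "unfolded")
  out
}

# ridge-regularized inverse: add eps * tr(Sigma)/p * I when the condition
# number exceeds condMax (pruning alone may not fix conditioning on
# arbitrary inputs)
.regularizedInverse <- function(sigma, eps = 1e-6, condMax = 1e10) {
  p <- nrow(sigma)
  reg <- FALSE
  kap <- tryCatch(suppressWarnings(kappa(sigma, exact = TRUE)),
                  error = function(e) Inf)
  if (!is.finite(kap) || kap > condMax) {
    sigma <- sigma + diag(eps * sum(diag(sigma)) / p, p)
    reg <- TRUE
  }
  inv <- tryCatch(solve(sigma), error = function(e) NULL)
  if (is.null(inv)) {
    sigma <- sigma + diag(max(eps * sum(diag(sigma)) / p, 1e-12), p)
    inv <- tryCatch(solve(sigma), error = function(e)
      stop("state covariance singular even after ridge regularization; ",
           "prune descriptors more aggressively"))
    reg <- TRUE
  }
  list(inv = inv, regularized = reg)
}

#' Harmonic within-class scatter
#'
#' \eqn{S_w = (\Sigma_F^{-1} + \Sigma_U^{-1})^{-1}}: the harmonic average
#' of the state covariances, which penalises directions that fluctuate
#' little in either basin.
#'
#' @param sigmaF,sigmaU state covariance matrices (square, equal size).
#' @return the symmetric positive-definite matrix \eqn{S_w}.
#' @examples
#' harmonicWithinScatter(diag(2), diag(2))  # 0.5 * I
#' @export
harmonicWithinScatter <- function(sigmaF, sigmaU) {
  sigmaF <- as.matrix(sigmaF); sigmaU <- as.matrix(sigmaU)
  stopifnot(identical(dim(sigmaF), dim(sigmaU)))
  iF <- .regularizedInverse(sigmaF)
  iU <- .regularizedInverse(sigmaU)
  sw <- .regularizedInverse(iF$inv + iU$inv)$inv
  (sw + t(sw)) / 2
}

#' Between-class scatter for two states
#'
#' \eqn{S_b = \frac{1}{2} (\mu_F - \mu_U)(\mu_F - \mu_U)^\top}; rank
#' \eqn{\le 1}.
#'
#' @param muF,muU state mean vectors of equal length.
#' @return the rank-\eqn{\le 1} matrix \eqn{S_b}.
#' @export
betweenScatter <- function(muF, muU) {
  stopifnot(length(muF) == length(muU))
  d <- as.numeric(muF - muU)
  0.5 * tcrossprod(d)
}

#' Solve the two-state HLDA problem
#'
#' Computes the leading eigenpair of \eqn{S_w^{-1} S_b}. For two states
#' the closed form is used: \eqn{W \propto S_w^{-1}(\mu_F - \mu_U)},
#' \eqn{\lambda = \frac{1}{2}\Delta\mu^\top S_w^{-1} \Delta\mu}. The
#' returned weights are unit-norm with the sign fixed so that the CV
#' increases from folded to unfolded (\eqn{W^\top \mu_U > W^\top \mu_F}).
#' \code{method = "eigen"} solves the generalized eigenproblem densely
#' instead (fallback kept for cross-checking and multi-state extension).
#'
#' @param stats a list with elements \code{folded} and \code{unfolded} of
#'   [StateStats-class] (as returned by [stateStatistics()]).
#' @param method \code{"closed-form"} (default) or \code{"eigen"}.
#' @param tol eigenvalues below this are flagged as "no separation".
#' @return an [HLDAModel-class].
#' @examples
#' s <- list(
#'   folded = new("StateStats", state = "folded", mu = c(0, 0),
#'                sigma = diag(c(1, 4)), n = 100L, regularized = FALSE),
#'   unfolded = new("StateStats", state = "unfolded", mu = c(1, 1),
#'                  sigma = diag(c(2, 2)), n = 100L, regularized = FALSE))
#' hldaEigenvalue(solveHLDA(s))  # 1.125
#' @export
solveHLDA <- function(stats, method = c("closed-form", "eigen"),
                      tol = .Machine$double.eps^0.5) {
  method <- match.arg(method)
  stopifnot(is.list(stats), all(c("folded", "unfolded") %in% names(stats)))
  f <- stats$folded; u <- stats$unfolded
  stopifnot(is(f, "StateStats"), is(u, "StateStats"))
  p <- length(f@mu)
  dmu <- f@mu - u@mu
  sw <- harmonicWithinScatter(f@sigma, u@sigma)
  sb <- betweenScatter(f@mu, u@mu)
  swInvDmu <- solve(sw, dmu)
  if (method == "closed-form") {
    lambda <- 0.5 * sum(dmu * swInvDmu)
    w <- swInvDmu
  } else {
    es <- eigen(solve(sw) %*% sb)
    lambda <- Re(es$values[1L])
    w <- Re(es$vectors[, 1L])
  }
  labels <- if (!is.null(names(f@mu))) names(f@mu) else sprintf("d%d", 1:p)
  pairs <- tryCatch(parsePairLabels(labels),
                    error = function(e)
                      data.frame(p = seq_len(p), q = rep(NA_integer_, p),
                                 label = labels, stringsAsFactors = FALSE))
  noSep <- lambda < tol
  if (noSep) {
    w <- rep(0, p)
  } else {
    w <- w / sqrt(sum(w^2))
    if (sum(w * u@mu) <= sum(w * f@mu)) w <- -w
  }
  names(w) <- labels
  mdl <- new("HLDAModel",
             weights = w, lambda = max(lambda, 0), Sw = sw, Sb = sb,
             muF = f@mu, muU = u@mu, globalMean = (f@mu + u@mu) / 2,
             pairs = pairs,
             signConvention = "CV increases folded -> unfolded (W'muU > W'muF)",
             noSeparation = noSep)
  if (noSep)
    warning("no separation: lambda below tolerance; model flagged")
  mdl
}

#' Fit an HLDA collective variable from a labelled descriptor matrix
#'
#' Convenience wrapper: optional pruning, state statistics, and the
#' two-state HLDA solve in one call.
#'
#' @param x a [DescriptorMatrix-class].
#' @param labels state labels (see [stateStatistics()]).
#' @param prune prune descriptors first? Default TRUE.
#' @param cutoff Spearman pruning cutoff (default 0.93).
#' @param ... passed to [solveHLDA()].
#' @return an [HLDAModel-class].
#' @export
fitHLDA <- function(x, labels = NULL, prune = TRUE, cutoff = 0.93, ...) {
  if (prune) {
    if (is.null(frameStates(x)) && !is.null(labels)) {
      lab <- if (is(labels, "StateLabels")) as.character(stateAssignments(labels))
             else as.character(labels)
      frameStates(x) <- lab
      labels <- NULL
    }
    x <- pruneDescriptors(x, cutoff = cutoff)$matrix
  }
  solveHLDA(stateStatistics(x, labels), ...)
}

#' Project configurations onto an HLDA collective variable
#'
#' \eqn{s(R) = \sum_{p<q} W_{pq} d_{pq}(R)}: the per-frame dot product of
#' the descriptor values with the CV weights. Columns are matched to the
#' model by pair label, order-insensitively.
#'
#' @param x a [DescriptorMatrix-class].
#' @param model an [HLDAModel-class].
#' @return numeric CV series, one value per frame.
#' @export
projectCV <- function(x, model) {
  stopifnot(is(x, "DescriptorMatrix"), is(model, "HLDAModel"))
  need <- names(model@weights)
  have <- pairLabels(x)
  missing <- setdiff(need, have)
  if (length(missing))
    stop("descriptor matrix lacks model descriptor(s): ",
         paste(missing, collapse = ", "))
  v <- descriptorValues(x)[, need, drop = FALSE]
  as.numeric(v %*% model@weights)
}
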