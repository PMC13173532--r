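# Shared fixtures, all built in code.

# StateStats pair from explicit moments
statsPair <- function(muF, muU, sigmaF, sigmaU, n = 100L) {
  list(
    folded = new("StateStats", state = "folded", mu = muF,
                 sigma = as.matrix(sigmaF), n = n, regularized = FALSE),
    unfolded = new("StateStats", state = "unfolded", mu = muU,
                   sigma = as.matrix(sigmaU), n = n, regularized = FALSE)
  )
}

# random symmetric positive-definite matrix
randomSPD <- function(p, jitter = 0.5) {
  a <- matrix(rnorm(p * p), p, p)
  crossprod(a) + diag(jitter, p)
}

# reference eigenvalue from the dense generalized eigenproblem Sb W = l Sw W
eigenLambda <- function(muF, muU, sigmaF, sigmaU) {
  sw <- solve(solve(sigmaF) + solve(sigmaU))
  sb <- 0.5 * tcrossprod(muF - muU)
  es <- eigen(solve(sw) %*% sb)
  list(lambda = Re(es$values[1L]), w = Re(es$vectors[, 1L]), sw = sw)
}

# labelled two-Gaussian descriptor matrix drawn from explicit moments
gaussianDescriptors <- function(muF, muU, sigmaF, sigmaU, nPerState,
                                labels = sprintf("d_1_%d", 2 + seq_along(muF))) {
  p <- length(muF)
  cf <- chol(sigmaF); cu <- chol(sigmaU)
  vF <- matrix(rnorm(nPerState * p), nPerState, p) %*% cf +
    matrix(muF, nPerState, p, byrow = TRUE)
  vU <- matrix(rnorm(nPerState * p), nPerState, p) %*% cu +
    matrix(muU, nPerState, p, byrow = TRUE)
  vals <- rbind(vF, vU)
  colnames(vals) <- labels
  DescriptorMatrix(vals, pairs = parsePairLabels(labels),
                   state = rep(c("folded", "unfolded"), each = nPerState))
}

# state-restricted descriptor ensembles from a toy spec: short runs started
# in each basin (barrier high enough that no transition occurs)
basinDescriptors <- function(spec, nPerState, seed) {
  a <- spec@wellSeparation
  trF <- simulateDoubleWell(spec, nPerState - 1L, x0 = -a, seed = seed)
  trU <- simulateDoubleWell(spec, nPerState - 1L, x0 = +a, seed = seed + 1L)
  vals <- rbind(descriptorValues(mapToDescriptors(trF, spec, seed = seed + 2L)),
                descriptorValues(mapToDescriptors(trU, spec, seed = seed + 3L)))
  DescriptorMatrix(vals, pairs = spec@pairs,
                   state = rep(c("folded", "unfolded"), each = nPerState))
}

# random proper rigid motion applied to an N x 3 coordinate matrix
rigidMotion <- function(x) {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  sweep(x %*% q, 2L, rnorm(3, sd = 5), `+`)
}

# independent RMSD oracle: direct numeric minimization over rotations
# (Euler angles, multi-start grid + Nelder-Mead refinement)
numericRMSD <- function(mobile, ref) {
  a <- sweep(mobile, 2L, colMeans(mobile))
  b <- sweep(ref, 2L, colMeans(ref))
  rotmat <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    rz %*% ry %*% rx
  }
  f <- function(ang) sqrt(mean(rowSums((a %*% rotmat(ang) - b)^2)))
  starts <- as.matrix(expand.grid(a1 = c(0, pi / 2, pi, 3 * pi / 2),
                                  a2 = c(-pi / 3, 0, pi / 3, pi),
                                  a3 = c(0, pi / 2, pi, 3 * pi / 2)))
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    o <- optim(starts[i, ], f, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 2000))
    if (o$value < best) best <- o$value
  }
  best
}

# small non-degenerate reference structures (10 atoms)
refHelix <- function(n = 10L) {
  t <- seq_len(n)
  cbind(cos(t), sin(t), 0.3 * t)
}

refExtended <- function(n = 10L) {
  t <- seq_len(n)
  cbind(0.9 * t, 0.1 * sin(2 * t), 0.05 * t)
}
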