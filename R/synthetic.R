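## Synthetic two-state generator: latent double-well Langevin dynamics
## mapped to descriptor space, with optional Gaussian-hill biasing. Stands
## in for state-restricted and bias-accelerated MD of a small two-state
## folder, at the level of its statistics: two unimodal basins in descriptor
## space, one dominant slow mode, exponential first-passage times.

# evaluate expr under a given seed without disturbing the caller's RNG
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Construct a synthetic two-state system specification
#'
#' The latent dynamics is an overdamped Langevin process in the double well
#' \eqn{U(x) = \Delta U ((x/a)^2 - 1)^2} with minima at \eqn{\pm a} and
#' barrier \eqn{\Delta U} (in kT). Descriptors emulate residue-pair
#' backbone distances: \eqn{d_j = \mathrm{offset}_j + b_j x + \epsilon_j}.
#' Defaults give a ten-residue system with all 36 pairs of sequence
#' separation \eqn{\ge 2}, a 5 kT barrier, and signal-to-noise typical of
#' within-basin distance fluctuations of a small peptide.
#'
#' @param barrierHeight \eqn{\Delta U} in kT (> 0).
#' @param wellSeparation \eqn{a} (> 0); latent minima at \eqn{\pm a}.
#' @param friction \eqn{\gamma} (inverse time, > 0).
#' @param kT thermal energy (reduced units; default 1).
#' @param nResidues number of residues labelling the descriptor pairs.
#' @param minSeparation minimum sequence separation of the pairs.
#' @param loadings per-descriptor slope \eqn{b_j}; a scalar is recycled.
#' @param offsets per-descriptor baseline; a scalar is recycled.
#' @param noiseSD per-descriptor noise s.d.; a scalar is recycled.
#' @param pairs optional pair table (see [pairTable()]); overrides
#'   \code{nResidues}/\code{minSeparation}.
#' @return a [TwoStateToySpec-class].
#' @examples
#' spec <- twoStateSpec(barrierHeight = 5, wellSeparation = 1)
#' spec
#' @export
twoStateSpec <- function(barrierHeight = 5, wellSeparation = 1, friction = 1,
                         kT = 1, nResidues = 10L, minSeparation = 2L,
                         loadings = 0.3, offsets = 1, noiseSD = 0.2,
                         pairs = NULL) {
  if (is.null(pairs)) pairs <- pairTable(nResidues, minSeparation)
  np <- nrow(pairs)
  rec <- function(v) {
    if (length(v) == 1L) rep(as.numeric(v), np) else as.numeric(v)
  }
  new("TwoStateToySpec",
      barrierHeight = as.numeric(barrierHeight),
      wellSeparation = as.numeric(wellSeparation),
      friction = as.numeric(friction), kT = as.numeric(kT),
      loadings = rec(loadings), offsets = rec(offsets),
      noiseSD = rec(noiseSD), pairs = pairs,
      nResidues = as.integer(nResidues))
}

# barrier in energy units and stability bound on dt
.dUenergy <- function(spec) spec@barrierHeight * spec@kT

#' Stable default integration time step for a spec
#'
#' The Euler-Maruyama step must satisfy
#' \eqn{\Delta t \cdot \max|U''| / \gamma < 0.1}; the stiffest curvature at
#' equilibrium is \eqn{U''(\pm a) = 8 \Delta U / a^2}. The default applies a
#' safety factor well inside that bound.
#'
#' @param spec a [TwoStateToySpec-class].
#' @param safety fraction of the stability bound to use (default 0.08).
#' @return a time step.
#' @export
defaultTimestep <- function(spec, safety = 0.08) {
  stopifnot(is(spec, "TwoStateToySpec"), safety > 0, safety < 0.1)
  safety * spec@friction * spec@wellSeparation^2 / (8 * .dUenergy(spec))
}

.checkStability <- function(spec, dt) {
  maxcurv <- 8 * .dUenergy(spec) / spec@wellSeparation^2
  if (dt * maxcurv / spec@friction >= 0.1)
    stop(sprintf(paste0(
      "dt = %g too large for spec (dU = %g kT, a = %g, gamma = %g): ",
      "need dt * 8 dU / (a^2 gamma) < 0.1, i.e. dt < %g"),
      dt, spec@barrierHeight, spec@wellSeparation, spec@friction,
      0.1 * spec@friction * spec@wellSeparation^2 / (8 * .dUenergy(spec))))
  invisible(dt)
}

#' Simulate the unbiased latent double well
#'
#' Overdamped Euler-Maruyama integration of
#' \eqn{\dot x = -U'(x)/\gamma + \sqrt{2 kT/\gamma}\,\eta(t)}. The long-run
#' stationary law is Boltzmann, \eqn{\propto e^{-U(x)/kT}}. Bitwise
#' reproducible for a given (spec, seed).
#'
#' @param spec a [TwoStateToySpec-class].
#' @param nSteps number of integration steps (\eqn{\ge 1}).
#' @param dt time step; default [defaultTimestep()].
#' @param x0 initial latent position (default: the folded minimum
#'   \eqn{-a}).
#' @param seed integer seed.
#' @param recordStride record every this-many steps (frame 0 always
#'   recorded); integration always uses \code{dt}.
#' @return a [LatentTrajectory-class].
#' @examples
#' tr <- simulateDoubleWell(twoStateSpec(), nSteps = 1000, seed = 1)
#' range(latentX(tr))
#' @export
simulateDoubleWell <- function(spec, nSteps, dt = defaultTimestep(spec),
                               x0 = -spec@wellSeparation, seed,
                               recordStride = 1L) {
  stopifnot(is(spec, "TwoStateToySpec"), nSteps >= 1, recordStride >= 1)
  .checkStability(spec, dt)
  out <- .withSeed(seed, sim_double_well_cpp(
    .dUenergy(spec), spec@wellSeparation, spec@friction, spec@kT,
    as.numeric(nSteps), dt, x0, as.integer(recordStride)))
  if (out$unstable)
    stop(sprintf(paste0("integration unstable (|x| exceeded 10 a) with dt ",
                        "= %g for spec with dU = %g kT, a = %g; reduce dt"),
                 dt, spec@barrierHeight, spec@wellSeparation))
  x <- out$x
  new("LatentTrajectory",
      times = (seq_along(x) - 1) * dt * recordStride, x = x, dt = dt,
      seed = as.integer(seed))
}

#' Map a latent trajectory into descriptor space
#'
#' Applies the generative model
#' \eqn{d_j(t) = \mathrm{offset}_j + b_j x(t) + \epsilon_j(t)},
#' \eqn{\epsilon_j \sim N(0, \sigma_j^2)} i.i.d. per frame, producing the
#' two-Gaussian within-basin descriptor structure that HLDA assumes.
#'
#' @param latent a [LatentTrajectory-class].
#' @param spec the generating [TwoStateToySpec-class].
#' @param seed integer seed for the descriptor noise.
#' @return a [DescriptorMatrix-class] (frames from the trajectory).
#' @export
mapToDescriptors <- function(latent, spec, seed) {
  stopifnot(is(latent, "LatentTrajectory"), is(spec, "TwoStateToySpec"))
  n <- length(latent@x)
  p <- nrow(spec@pairs)
  vals <- outer(latent@x, spec@loadings) +
    matrix(spec@offsets, n, p, byrow = TRUE)
  if (any(spec@noiseSD > 0)) {
    eps <- .withSeed(seed, matrix(rnorm(n * p), n, p))
    vals <- vals + sweep(eps, 2L, spec@noiseSD, `*`)
  }
  colnames(vals) <- spec@pairs$label
  DescriptorMatrix(vals, pairs = spec@pairs)
}

#' Derive a mutant specification
#'
#' Models a point mutation as a named set of additive parameter deltas on
#' the two-state spec (e.g. barrier height, well separation, or individual
#' loading entries). The input spec is unchanged.
#'
#' @param spec a [TwoStateToySpec-class].
#' @param perturbation named list of deltas; names among
#'   \code{barrierHeight}, \code{wellSeparation}, \code{friction},
#'   \code{kT}, \code{loadings}, \code{offsets}, \code{noiseSD}. Vector
#'   fields accept a scalar (applied to all entries) or a full-length
#'   vector.
#' @return a new, validated [TwoStateToySpec-class].
#' @examples
#' mut <- makeMutant(twoStateSpec(), list(wellSeparation = 0.5))
#' @export
makeMutant <- function(spec, perturbation = list()) {
  stopifnot(is(spec, "TwoStateToySpec"), is.list(perturbation))
  allowed <- c("barrierHeight", "wellSeparation", "friction", "kT",
               "loadings", "offsets", "noiseSD")
  bad <- setdiff(names(perturbation), allowed)
  if (length(bad))
    stop("unknown perturbation field(s): ", paste(bad, collapse = ", "))
  out <- spec
  for (nm in names(perturbation)) {
    delta <- perturbation[[nm]]
    cur <- slot(out, nm)
    if (length(delta) != 1L && length(delta) != length(cur))
      stop("perturbation '", nm, "' must be scalar or length ", length(cur))
    slot(out, nm) <- cur + delta
  }
  if (out@barrierHeight <= 0 || out@wellSeparation <= 0)
    stop("perturbation would produce a non-positive barrier or separation")
  validObject(out)
  out
}

#' Run a Gaussian-hill biased escape from the folded basin
#'
#' Evolves the latent dynamics under \eqn{U + V_{bias}} where hills are
#' deposited along the linear CV \eqn{s = W^\top d(x)} (noise-free
#' descriptor image, so \eqn{s = c_0 + c_1 x} with
#' \eqn{c_1 = W^\top b}). Records the bias energy experienced at every
#' frame, the hill log, and the biased and rescaled first-passage times to
#' the stop criterion.
#'
#' @param spec a [TwoStateToySpec-class].
#' @param cvWeights unit-norm weight vector over the spec's descriptor
#'   pairs (optionally named by pair label).
#' @param hillHeight hill height in kT (default 0.5; \eqn{\ge 0}).
#' @param hillWidth hill width in CV units; default
#'   \eqn{0.2\, a\, \lVert b \rVert}.
#' @param pace hills per unit time (default 1).
#' @param stopOn \code{"latent"} (threshold on \eqn{x}) or \code{"cv"}
#'   (threshold on \eqn{s}).
#' @param stopThreshold first passage is the first frame with the stop
#'   coordinate \eqn{\ge} this value (default: the barrier top, latent 0).
#' @param biasFactor optional well-tempered bias factor (> 1); NULL =
#'   standard metadynamics.
#' @param maxSteps step cap; reaching it without crossing is not an error,
#'   the run is flagged uncrossed.
#' @param dt integration step; default [defaultTimestep()].
#' @param x0 start position (default the folded minimum).
#' @param seed integer seed.
#' @param recordStride recording stride for the frame series.
#' @return a [BiasedRun-class].
#' @export
runBiasedEscape <- function(spec, cvWeights, hillHeight = 0.5,
                            hillWidth = NULL, pace = 1,
                            stopOn = c("latent", "cv"), stopThreshold = 0,
                            biasFactor = NULL, maxSteps = 1e6,
                            dt = defaultTimestep(spec),
                            x0 = -spec@wellSeparation, seed,
                            recordStride = 1L) {
  stopifnot(is(spec, "TwoStateToySpec"), hillHeight >= 0, pace > 0)
  stopOn <- match.arg(stopOn)
  .checkStability(spec, dt)
  p <- nrow(spec@pairs)
  w <- .matchWeights(cvWeights, spec@pairs$label)
  if (abs(sqrt(sum(w^2)) - 1) > 1e-6)
    stop("cvWeights must be unit-norm")
  c0 <- sum(w * spec@offsets)
  c1 <- sum(w * spec@loadings)
  if (is.null(hillWidth))
    hillWidth <- 0.2 * spec@wellSeparation * sqrt(sum(spec@loadings^2))
  stopifnot(hillWidth > 0)
  bf <- if (is.null(biasFactor)) 0 else as.numeric(biasFactor)
  if (bf != 0 && bf <= 1) stop("biasFactor must be > 1")
  out <- .withSeed(seed, biased_escape_cpp(
    .dUenergy(spec), spec@wellSeparation, spec@friction, spec@kT, dt, x0,
    c0, c1, hillHeight * spec@kT, hillWidth, pace, bf,
    stopOn == "cv", stopThreshold, as.numeric(maxSteps),
    as.integer(recordStride)))
  if (out$unstable)
    stop(sprintf("biased integration unstable with dt = %g; reduce dt or hillHeight",
                 dt))
  x <- out$x
  traj <- new("LatentTrajectory",
              times = (seq_along(x) - 1) * dt * recordStride, x = x, dt = dt,
              seed = as.integer(seed))
  elapsed <- if (out$crossed) out$fpt else maxSteps * dt
  alpha <- if (elapsed > 0) out$tstar / elapsed else 1
  new("BiasedRun",
      trajectory = traj, biasEnergy = out$V, cv = c0 + c1 * x,
      hills = data.frame(time = out$hill_time, center = out$hill_center,
                         height = out$hill_height,
                         width = rep(hillWidth, length(out$hill_time))),
      crossed = out$crossed,
      biasedFPT = if (out$crossed) out$fpt else NA_real_,
      rescaledFPT = if (out$crossed) out$tstar else NA_real_,
      accelFactor = max(alpha, 1))
}

# match a (possibly named) weight vector against pair labels
.matchWeights <- function(w, labels) {
  if (!is.null(names(w))) {
    missing <- setdiff(labels, names(w))
    if (length(missing))
      stop("cvWeights missing descriptor(s): ",
           paste(missing, collapse = ", "))
    w <- w[labels]
  } else if (length(w) != length(labels)) {
    stop("cvWeights length ", length(w), " != descriptor count ",
         length(labels))
  }
  as.numeric(w)
}

#' State-restricted training data from a two-state spec
#'
#' Emulates the state-restricted sampling protocol: one short unbiased run
#' started in each basin, descriptor mapping, and frame labelling with an
#' exclusion band so that spontaneous partial excursions over the barrier
#' do not cross-contaminate the training ensembles. Labels use the latent
#' progress coordinate with folded cutoff \eqn{-f a} and unfolded cutoff
#' \eqn{+f a} (band fraction \eqn{f}).
#'
#' @param spec a [TwoStateToySpec-class].
#' @param nFramesPerState frames recorded per basin run (default 4000).
#' @param bandFraction half-width of the exclusion band as a fraction of
#'   the well separation (default 0.4).
#' @param recordStride integration steps between recorded frames (default
#'   10, about one well correlation time, so recorded frames are roughly
#'   independent -- the analog of saving MD frames at intervals).
#' @param seed integer seed (four sub-seeds are derived from it).
#' @return a labelled [DescriptorMatrix-class] (states folded / excluded /
#'   unfolded).
#' @export
basinTrainingData <- function(spec, nFramesPerState = 4000L,
                              bandFraction = 0.4, recordStride = 10L, seed) {
  stopifnot(is(spec, "TwoStateToySpec"), bandFraction > 0, bandFraction < 1)
  a <- spec@wellSeparation
  nSteps <- (nFramesPerState - 1L) * recordStride
  trF <- simulateDoubleWell(spec, nSteps, x0 = -a, seed = seed,
                            recordStride = recordStride)
  trU <- simulateDoubleWell(spec, nSteps, x0 = +a, seed = seed + 1L,
                            recordStride = recordStride)
  x <- c(latentX(trF), latentX(trU))
  lab <- stateAssignments(assignStates(x, tF = -bandFraction * a,
                                       tU = bandFraction * a))
  vals <- rbind(descriptorValues(mapToDescriptors(trF, spec, seed = seed + 2L)),
                descriptorValues(mapToDescriptors(trU, spec, seed = seed + 3L)))
  DescriptorMatrix(vals, pairs = spec@pairs, state = as.character(lab))
}

#' Brute-force unbiased first-passage sample
#'
#' Repeatedly integrates the unbiased dynamics from \code{x0} and records
#' the first-passage time to \code{threshold} (latent coordinate). The
#' reference estimate that bias-accelerated, rescaled kinetics is validated
#' against.
#'
#' @param spec a [TwoStateToySpec-class].
#' @param nEvents number of independent escape events.
#' @param threshold latent first-passage threshold (default 0, the barrier
#'   top).
#' @param dt time step; default [defaultTimestep()].
#' @param x0 start position (default the folded minimum).
#' @param maxStepsPerEvent cap per event; uncrossed events yield NA.
#' @param seed integer seed.
#' @return numeric vector of first-passage times (NA where uncrossed).
#' @export
bruteForceFPT <- function(spec, nEvents, threshold = 0,
                          dt = defaultTimestep(spec),
                          x0 = -spec@wellSeparation,
                          maxStepsPerEvent = 1e8, seed) {
  stopifnot(is(spec, "TwoStateToySpec"), nEvents >= 1)
  .checkStability(spec, dt)
  .withSeed(seed, vapply(seq_len(nEvents), function(i) {
    out <- unbiased_fpt_cpp(.dUenergy(spec), spec@wellSeparation,
                            spec@friction, spec@kT, dt, x0, threshold,
                            as.numeric(maxStepsPerEvent))
    if (out$unstable) stop("unbiased integration unstable; reduce dt")
    if (out$crossed) out$fpt else NA_real_
  }, numeric(1)))
}

#' Generate toy multi-frame coordinates from two reference structures
#'
#' Each frame is the designated reference (folded or unfolded) plus
#' isotropic Gaussian jitter on every atom. Used as a fixture generator for
#' superposition, labelling and descriptor tests.
#'
#' @param refFolded,refUnfolded N x 3 coordinate matrices with identical
#'   atom counts.
#' @param occupancy character/factor vector over frames, entries
#'   \code{"folded"} or \code{"unfolded"}.
#' @param fluctuationSD isotropic per-coordinate jitter s.d. (\eqn{\ge 0}).
#' @param seed integer seed.
#' @return a frames x atoms x 3 array.
#' @export
generateToyCoordinates <- function(refFolded, refUnfolded, occupancy,
                                   fluctuationSD = 0, seed) {
  refFolded <- as.matrix(refFolded)
  refUnfolded <- as.matrix(refUnfolded)
  if (!identical(dim(refFolded), dim(refUnfolded)))
    stop("reference structures must have identical atom counts")
  stopifnot(ncol(refFolded) == 3L, fluctuationSD >= 0)
  occupancy <- as.character(occupancy)
  if (!all(occupancy %in% c("folded", "unfolded")))
    stop("occupancy entries must be 'folded' or 'unfolded'")
  n <- length(occupancy)
  nat <- nrow(refFolded)
  frames <- array(NA_real_, c(n, nat, 3L))
  .withSeed(seed, for (i in seq_len(n)) {
    ref <- if (occupancy[i] == "folded") refFolded else refUnfolded
    frames[i, , ] <- ref +
      if (fluctuationSD > 0) matrix(rnorm(nat * 3L, 0, fluctuationSD), nat, 3L)
      else 0
  })
  frames
}
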