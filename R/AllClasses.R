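## S4 class definitions and validity. Constructors live with their modules.

#' TwoStateToySpec: parameters of the synthetic double-well system
#'
#' Defines a latent double-well Langevin system,
#' \eqn{U(x) = \Delta U \, ((x/a)^2 - 1)^2}, together with the linear map
#' from the latent coordinate onto a set of residue-pair distance
#' descriptors, \eqn{d_j(t) = \mathrm{offset}_j + b_j x(t) + \epsilon_j},
#' \eqn{\epsilon_j \sim N(0, \sigma_j^2)}. A "mutation" of the system is a
#' change to \eqn{\Delta U}, \eqn{a} or entries of \eqn{b}
#' (see [makeMutant()]).
#'
#' @slot barrierHeight \eqn{\Delta U}, barrier height in units of kT (> 0).
#' @slot wellSeparation \eqn{a}: the minima sit at \eqn{\pm a} (latent
#'   length units, > 0).
#' @slot friction \eqn{\gamma}, inverse-time friction of the overdamped
#'   dynamics (> 0).
#' @slot kT thermal energy in reduced units (> 0; default 1).
#' @slot loadings per-descriptor slope \eqn{b_j} (latent-to-descriptor).
#' @slot offsets per-descriptor baseline.
#' @slot noiseSD per-descriptor Gaussian noise s.d. (\eqn{\ge 0}).
#' @slot pairs residue-pair table labelling descriptors (see [pairTable()]).
#' @slot nResidues number of residues the pair labels refer to.
#' @seealso [twoStateSpec()], [simulateDoubleWell()], [mapToDescriptors()]
#' @export
setClass("TwoStateToySpec",
  representation(
    barrierHeight = "numeric",
    wellSeparation = "numeric",
    friction = "numeric",
    kT = "numeric",
    loadings = "numeric",
    offsets = "numeric",
    noiseSD = "numeric",
    pairs = "data.frame",
    nResidues = "integer"
  )
)

setValidity("TwoStateToySpec", function(object) {
  msg <- character()
  if (length(object@barrierHeight) != 1L || !is.finite(object@barrierHeight) ||
      object@barrierHeight <= 0)
    msg <- c(msg, "barrierHeight must be a single positive number")
  if (length(object@wellSeparation) != 1L ||
      !is.finite(object@wellSeparation) || object@wellSeparation <= 0)
    msg <- c(msg, "wellSeparation must be a single positive number")
  if (length(object@friction) != 1L || object@friction <= 0)
    msg <- c(msg, "friction must be a single positive number")
  if (length(object@kT) != 1L || object@kT <= 0)
    msg <- c(msg, "kT must be a single positive number")
  np <- nrow(object@pairs)
  if (length(object@loadings) != np)
    msg <- c(msg, "loadings length must equal the number of descriptor pairs")
  if (length(object@offsets) != np)
    msg <- c(msg, "offsets length must equal the number of descriptor pairs")
  if (length(object@noiseSD) != np)
    msg <- c(msg, "noiseSD length must equal the number of descriptor pairs")
  if (any(object@noiseSD < 0))
    msg <- c(msg, "noiseSD entries must be >= 0")
  if (!all(c("p", "q", "label") %in% names(object@pairs)))
    msg <- c(msg, "pairs must have columns p, q, label")
  if (length(msg)) msg else TRUE
})

#' LatentTrajectory: a discretised latent Langevin path
#'
#' @slot times uniform, strictly increasing time grid (frame 0 at time 0).
#' @slot x latent coordinate at each time point.
#' @slot dt integration time step used to generate the path (the grid
#'   spacing equals \code{dt} times the recording stride).
#' @slot seed integer seed the path was generated from.
#' @export
setClass("LatentTrajectory",
  representation(times = "numeric", x = "numeric", dt = "numeric",
                 seed = "integer")
)

setValidity("LatentTrajectory", function(object) {
  msg <- character()
  if (length(object@times) != length(object@x))
    msg <- c(msg, "times and x must have equal length")
  if (!.allFinite(object@x)) msg <- c(msg, "x must be finite")
  if (length(object@times) > 1L) {
    d <- diff(object@times)
    if (any(d <= 0)) msg <- c(msg, "time grid must be strictly increasing")
    if (diff(range(d)) > 1e-9 * max(d))
      msg <- c(msg, "time grid must be uniform")
  }
  if (length(msg)) msg else TRUE
})

#' BiasedRun: a Gaussian-hill biased escape trajectory
#'
#' Produced by [runBiasedEscape()]. Carries the latent trajectory, the bias
#' energy experienced along it (in kT units), the hill deposition log, and
#' the first-passage bookkeeping: the biased first-passage time, the
#' rescaled (physical) first-passage time
#' \eqn{t^* = \sum \Delta t\, e^{V/kT}} and the acceleration factor
#' \eqn{\alpha = t^*/\tau}.
#'
#' @slot trajectory a [LatentTrajectory-class].
#' @slot biasEnergy \eqn{V(s(t), t)} in kT units, one value per frame
#'   (non-negative).
#' @slot cv the CV value \eqn{s(t)} per frame.
#' @slot hills data.frame log of deposited hills: time, center, height
#'   (kT), width (CV units).
#' @slot crossed whether the stop criterion was reached.
#' @slot biasedFPT biased first-passage time (NA if not crossed).
#' @slot rescaledFPT rescaled first-passage time \eqn{t^*} (NA if not
#'   crossed).
#' @slot accelFactor acceleration factor \eqn{\alpha \ge 1}.
#' @export
setClass("BiasedRun",
  representation(
    trajectory = "LatentTrajectory",
    biasEnergy = "numeric",
    cv = "numeric",
    hills = "data.frame",
    crossed = "logical",
    biasedFPT = "numeric",
    rescaledFPT = "numeric",
    accelFactor = "numeric"
  )
)

setValidity("BiasedRun", function(object) {
  msg <- character()
  if (any(object@biasEnergy < -1e-12))
    msg <- c(msg, "biasEnergy must be non-negative")
  if (length(object@biasEnergy) != length(object@trajectory@x))
    msg <- c(msg, "biasEnergy must have one value per frame")
  if (isTRUE(object@crossed) && is.finite(object@accelFactor) &&
      object@accelFactor < 1 - 1e-9)
    msg <- c(msg, "acceleration factor must be >= 1")
  if (length(msg)) msg else TRUE
})

#' StateLabels: folded/unfolded/excluded assignment of frames
#'
#' Frames with RMSD \eqn{\le t_F} are folded, RMSD \eqn{\ge t_U} unfolded,
#' and the band in between is excluded to avoid cross-contamination of the
#' state-restricted training ensembles.
#'
#' @slot labels factor with levels \code{folded}, \code{excluded},
#'   \code{unfolded}, one per frame.
#' @slot rmsd the RMSD series the labels were derived from.
#' @slot tF folded cutoff (same units as \code{rmsd}).
#' @slot tU unfolded cutoff; \code{tF < tU}.
#' @export
setClass("StateLabels",
  representation(labels = "factor", rmsd = "numeric", tF = "numeric",
                 tU = "numeric")
)

setValidity("StateLabels", function(object) {
  msg <- character()
  if (!identical(levels(object@labels), c("folded", "excluded", "unfolded")))
    msg <- c(msg, "labels must have levels folded, excluded, unfolded")
  if (length(object@labels) != length(object@rmsd))
    msg <- c(msg, "one label per RMSD value required")
  if (!(object@tF < object@tU)) msg <- c(msg, "tF must be < tU")
  ok <- ifelse(object@rmsd <= object@tF, "folded",
        ifelse(object@rmsd >= object@tU, "unfolded", "excluded"))
  if (!identical(as.character(object@labels), ok))
    msg <- c(msg, "labels inconsistent with the RMSD rule")
  if (length(msg)) msg else TRUE
})

#' StateStats: per-state descriptor mean and covariance
#'
#' @slot state state name ("folded" or "unfolded").
#' @slot mu sample mean vector over the state-restricted frames.
#' @slot sigma unbiased (n - 1) sample covariance matrix.
#' @slot n number of frames used.
#' @slot regularized whether a ridge term was added for conditioning.
#' @export
setClass("StateStats",
  representation(state = "character", mu = "numeric", sigma = "matrix",
                 n = "integer", regularized = "logical")
)

setValidity("StateStats", function(object) {
  msg <- character()
  p <- length(object@mu)
  if (!all(dim(object@sigma) == c(p, p)))
    msg <- c(msg, "sigma dimensions must match mu length")
  if (max(abs(object@sigma - t(object@sigma))) > 1e-8 * (1 + max(abs(object@sigma))))
    msg <- c(msg, "sigma must be symmetric")
  if (length(msg)) msg else TRUE
})

#' HLDAModel: a harmonic linear discriminant collective variable
#'
#' The two-state HLDA solution: unit-norm weight vector \eqn{W} over the
#' kept descriptors, the leading eigenvalue \eqn{\lambda} (a dimensionless
#' folded/unfolded separation score), the within- and between-class scatter
#' matrices, the state means, and the sign convention (the CV increases from
#' folded to unfolded).
#'
#' @slot weights named unit-norm weight vector \eqn{W} (names = pair labels).
#' @slot lambda leading eigenvalue \eqn{\lambda \ge 0}.
#' @slot Sw within-class scatter (harmonic average of state covariances).
#' @slot Sb between-class scatter, rank \eqn{\le 1} for two states.
#' @slot muF,muU state mean vectors.
#' @slot globalMean \eqn{\bar\mu = (\mu_F + \mu_U)/2}.
#' @slot pairs residue-pair table for the kept descriptors.
#' @slot signConvention record of the convention applied.
#' @slot noSeparation TRUE when \eqn{\lambda} is below machine tolerance.
#' @export
setClass("HLDAModel",
  representation(
    weights = "numeric", lambda = "numeric", Sw = "matrix", Sb = "matrix",
    muF = "numeric", muU = "numeric", globalMean = "numeric",
    pairs = "data.frame", signConvention = "character",
    noSeparation = "logical"
  )
)

setValidity("HLDAModel", function(object) {
  msg <- character()
  p <- length(object@weights)
  if (!object@noSeparation && abs(sqrt(sum(object@weights^2)) - 1) > 1e-8)
    msg <- c(msg, "weights must have unit Euclidean norm")
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (!all(dim(object@Sw) == c(p, p)))
    msg <- c(msg, "Sw dimensions must match weights")
  if (!object@noSeparation) {
    sF <- sum(object@weights * object@muF)
    sU <- sum(object@weights * object@muU)
    if (sU <= sF)
      msg <- c(msg, "sign convention violated: need W'muU > W'muF")
  }
  if (length(msg)) msg else TRUE
})

#' ResidueImportanceProfile: per-residue kinetic importance scores
#'
#' \eqn{I_r}: the mean absolute CV weight over all kept descriptor pairs
#' involving residue \eqn{r}. The normalized copy divides by the maximum so
#' the top residue scores exactly 1. Residues present in the descriptor
#' universe but absent from every kept pair are reported as unscored (NA)
#' rather than zero.
#'
#' @slot residues residue indices.
#' @slot score raw \eqn{I_r} (NA for unscored residues).
#' @slot normalizedScore \eqn{I_r / \max_r I_r}.
#' @slot nPairs \eqn{|N_r|}, number of kept pairs touching each residue.
#' @slot allZero TRUE when every weight is zero (normalization skipped).
#' @export
setClass("ResidueImportanceProfile",
  representation(residues = "integer", score = "numeric",
                 normalizedScore = "numeric", nPairs = "integer",
                 allZero = "logical")
)

setValidity("ResidueImportanceProfile", function(object) {
  msg <- character()
  n <- length(object@residues)
  if (length(object@score) != n || length(object@normalizedScore) != n ||
      length(object@nPairs) != n)
    msg <- c(msg, "score, normalizedScore, nPairs must match residues")
  if (anyDuplicated(object@residues))
    msg <- c(msg, "each residue must appear once")
  if (any(object@score < 0, na.rm = TRUE)) msg <- c(msg, "I_r must be >= 0")
  sc <- object@normalizedScore[!is.na(object@normalizedScore)]
  if (!object@allZero && length(sc) &&
      (abs(max(sc) - 1) > 1e-12 || any(sc < 0 | sc > 1 + 1e-12)))
    msg <- c(msg, "normalized scores must lie in [0, 1] with max exactly 1")
  if (length(msg)) msg else TRUE
})

#' FPTRecord: one rescaled first-passage observation
#'
#' @slot biasedFPT biased first-passage time \eqn{\tau} (NA if the run never
#'   crossed; for unbiased records this is the plain FPT).
#' @slot accelFactor acceleration factor \eqn{\alpha \ge 1}.
#' @slot rescaledFPT \eqn{t^* = \alpha \tau}.
#' @slot crossed whether the stop criterion was reached.
#' @export
setClass("FPTRecord",
  representation(biasedFPT = "numeric", accelFactor = "numeric",
                 rescaledFPT = "numeric", crossed = "logical")
)

setValidity("FPTRecord", function(object) {
  msg <- character()
  if (is.finite(object@accelFactor) && object@accelFactor < 1 - 1e-9)
    msg <- c(msg, "acceleration factor must be >= 1")
  if (object@crossed && is.finite(object@rescaledFPT) &&
      object@rescaledFPT < object@biasedFPT - 1e-12 * max(1, object@biasedFPT))
    msg <- c(msg, "rescaled FPT must be >= biased FPT")
  if (length(msg)) msg else TRUE
})

#' MFPTEstimate: rate and MFPT from progressive exponential survival fits
#'
#' @slot rate fitted escape rate \eqn{k > 0} (inverse time).
#' @slot mfpt \eqn{1/k}.
#' @slot r2 \eqn{R^2} of the selected survival fit.
#' @slot mSelected number of fastest samples used by the selected fit.
#' @slot kMLE censored maximum-likelihood rate at the selected cutoff
#'   (cross-check estimator).
#' @slot nTotal,nCrossed total records and crossed records.
#' @slot scan the full cutoff scan: one row per m with k, R2.
#' @export
setClass("MFPTEstimate",
  representation(rate = "numeric", mfpt = "numeric", r2 = "numeric",
                 mSelected = "integer", kMLE = "numeric", nTotal = "integer",
                 nCrossed = "integer", scan = "data.frame")
)

setValidity("MFPTEstimate", function(object) {
  msg <- character()
  if (object@rate <= 0) msg <- c(msg, "rate must be > 0")
  if (abs(object@mfpt * object@rate - 1) > 1e-9)
    msg <- c(msg, "mfpt must equal 1/rate")
  if (object@mSelected > object@nCrossed)
    msg <- c(msg, "selected cutoff cannot exceed the number of crossings")
  if (object@r2 > 1 + 1e-12) msg <- c(msg, "R^2 cannot exceed 1")
  if (length(msg)) msg else TRUE
})

#' ParabolicBasinPair: two parabolic free-energy basins on a CV axis
#'
#' Marcus-style picture of the folded and unfolded basins:
#' \eqn{F_F(s) = \frac{1}{2}\kappa_F (s - s_F)^2} and
#' \eqn{F_U(s) = \Delta F + \frac{1}{2}\kappa_U (s - s_U)^2}. The barrier is
#' the free energy at their crossing point relative to the folded minimum.
#'
#' @slot sF,sU basin minima positions (CV units), \code{sF != sU}.
#' @slot kappaF,kappaU basin curvatures (energy / CV^2), both > 0.
#' @slot deltaF free-energy offset of the unfolded minimum (energy).
#' @export
setClass("ParabolicBasinPair",
  representation(sF = "numeric", sU = "numeric", kappaF = "numeric",
                 kappaU = "numeric", deltaF = "numeric")
)

setValidity("ParabolicBasinPair", function(object) {
  msg <- character()
  if (object@kappaF <= 0 || object@kappaU <= 0)
    msg <- c(msg, "curvatures must be > 0")
  if (object@sF == object@sU) msg <- c(msg, "sF and sU must differ")
  if (length(msg)) msg else TRUE
})

#' ScreeningReport: per-mutant lambda screening table
#'
#' @slot table one row per mutant: id, lambda, predicted direction
#'   (faster/slower/neutral relative to the reference), reliability flag and,
#'   when available, the WT importance of the mutated residue.
#' @slot referenceId identifier of the reference system.
#' @slot referenceLambda the reference eigenvalue.
#' @slot tolerance relative lambda half-width of the neutral band.
#' @export
setClass("ScreeningReport",
  representation(table = "data.frame", referenceId = "character",
                 referenceLambda = "numeric", tolerance = "numeric")
)

#' DescriptorMatrix: frames-by-descriptors distance features
#'
#' A thin [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment]
#' specialisation: rows are descriptors (residue-pair distances, with
#' \code{p}, \code{q} in \code{rowData}), columns are frames (with the
#' optional state label in \code{colData}). [descriptorValues()] returns the
#' conventional frames x descriptors matrix.
#'
#' @export
setClass("DescriptorMatrix", contains = "SummarizedExperiment")

setValidity("DescriptorMatrix", function(object) {
  msg <- character()
  rd <- rowData(object)
  if (!all(c("p", "q") %in% colnames(rd)))
    msg <- c(msg, "rowData must carry residue indices p and q")
  else {
    if (any(rd$p >= rd$q)) msg <- c(msg, "pairs must satisfy p < q")
    if (anyDuplicated(paste(rd$p, rd$q))) msg <- c(msg, "pair labels must be unique")
  }
  v <- assay(object)
  if (!all(is.finite(v))) msg <- c(msg, "descriptor values must be finite")
  if (length(msg)) msg else TRUE
})
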