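## Structural primitives: optimal-superposition RMSD, folded/unfolded state
## labelling with an exclusion band, first-passage detection.

#' Minimum RMSD under optimal rigid superposition (Kabsch)
#'
#' Root-mean-square deviation after centring both frames and rotating the
#' mobile one by the proper rotation (SVD with determinant correction; no
#' reflections) that minimises the deviation. Symmetric in its arguments
#' and invariant to rigid motions of either frame.
#'
#' @param mobile,reference N x 3 coordinate matrices, equal atom counts,
#'   \eqn{N \ge 3}.
#' @return the minimum RMSD (same length units as the input).
#' @examples
#' x <- matrix(rnorm(30), 10, 3)
#' kabschRMSD(x, x)  # 0
#' @export
kabschRMSD <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)))
    stop("atom-count mismatch: ", nrow(mobile), " vs ", nrow(reference))
  n <- nrow(mobile)
  if (n < 3L || ncol(mobile) != 3L)
    stop("need N x 3 coordinates with N >= 3")
  a <- sweep(mobile, 2L, colMeans(mobile))
  b <- sweep(reference, 2L, colMeans(reference))
  sb <- svd(b)
  if (sb$d[2L] <= 1e-10 * max(sb$d[1L], 1e-300))
    stop("degenerate reference: atoms are collinear (rank < 2)")
  s <- svd(crossprod(a, b))          # 3x3 cross-covariance
  d <- sign(det(s$u %*% t(s$v)))     # proper rotation only
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(sum((a %*% rot - b)^2) / n)
}

#' RMSD of every frame to a reference
#'
#' @param frames frames x atoms x 3 array (e.g. from
#'   [generateToyCoordinates()] or [readPDBFrames()]).
#' @param reference N x 3 reference coordinates.
#' @return numeric vector of per-frame Kabsch RMSDs.
#' @export
rmsdSeries <- function(frames, reference) {
  stopifnot(length(dim(frames)) == 3L)
  vapply(seq_len(dim(frames)[1L]),
         function(i) kabschRMSD(frames[i, , ], reference), numeric(1))
}

#' Assign folded/unfolded/excluded state labels from an RMSD series
#'
#' RMSD \eqn{\le t_F} is folded, RMSD \eqn{\ge t_U} is unfolded; frames in
#' the open band between are excluded so that the state-restricted training
#' ensembles are not cross-contaminated by barrier configurations.
#' Boundaries are inclusive on both sides.
#'
#' @param rmsd per-frame RMSD values.
#' @param tF folded cutoff.
#' @param tU unfolded cutoff; must exceed \code{tF}.
#' @return a [StateLabels-class].
#' @examples
#' stateAssignments(assignStates(c(0.20, 0.30, 0.60), tF = 0.25, tU = 0.57))
#' @export
assignStates <- function(rmsd, tF = 0.25, tU = 0.57) {
  if (!(tF < tU)) stop("tF must be < tU")
  stopifnot(is.numeric(rmsd), all(is.finite(rmsd)))
  lab <- ifelse(rmsd <= tF, "folded",
         ifelse(rmsd >= tU, "unfolded", "excluded"))
  new("StateLabels",
      labels = factor(lab, levels = c("folded", "excluded", "unfolded")),
      rmsd = as.numeric(rmsd), tF = tF, tU = tU)
}

#' First-passage time of an RMSD series over a threshold
#'
#' Time stamp of the first frame with RMSD \eqn{\ge} \code{tFPT}, with
#' frame 0 at time 0. Returns \code{NA} (with attribute
#' \code{crossed = FALSE}) when the threshold is never reached.
#'
#' @param rmsd per-frame RMSD series (non-empty).
#' @param dt time per frame (> 0).
#' @param tFPT first-passage RMSD threshold.
#' @return the first-passage time, or NA if not crossed; the logical
#'   attribute \code{crossed} is set either way.
#' @examples
#' firstPassageTime(c(0.1, 0.2, 0.4, 0.1, 0.6), dt = 1, tFPT = 0.36)  # 2
#' @export
firstPassageTime <- function(rmsd, dt, tFPT) {
  if (!length(rmsd)) stop("empty RMSD series")
  stopifnot(dt > 0)
  idx <- which(rmsd >= tFPT)
  if (!length(idx))
    return(structure(NA_real_, crossed = FALSE))
  structure((idx[1L] - 1) * dt, crossed = TRUE)
}
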