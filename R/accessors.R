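## Accessors and show methods.

#' @rdname hldaKinetics-generics
#' @export
setMethod("pairLabels", "TwoStateToySpec", function(x) x@pairs$label)

#' @rdname hldaKinetics-generics
#' @export
setMethod("pairLabels", "DescriptorMatrix", function(x) rownames(x))

#' @rdname hldaKinetics-generics
#' @export
setMethod("pairLabels", "HLDAModel", function(x) x@pairs$label)

#' @rdname hldaKinetics-generics
#' @export
setMethod("descriptorValues", "DescriptorMatrix",
          function(x) t(assay(x, "distances")))

#' @rdname hldaKinetics-generics
#' @export
setMethod("frameStates", "DescriptorMatrix", function(x) {
  cd <- colData(x)
  if ("state" %in% colnames(cd)) cd$state else NULL
})

#' @rdname hldaKinetics-generics
#' @export
setReplaceMethod("frameStates", "DescriptorMatrix", function(x, value) {
  stopifnot(length(value) == ncol(x))
  colData(x)$state <- as.character(value)
  x
})

#' @rdname hldaKinetics-generics
#' @export
setMethod("cvWeights", "HLDAModel", function(x) x@weights)

#' @rdname hldaKinetics-generics
#' @export
setMethod("hldaEigenvalue", "HLDAModel", function(x) x@lambda)

#' @rdname hldaKinetics-generics
#' @export
setMethod("timeGrid", "LatentTrajectory", function(x) x@times)

#' @rdname hldaKinetics-generics
#' @export
setMethod("latentX", "LatentTrajectory", function(x) x@x)

#' @rdname hldaKinetics-generics
#' @export
setMethod("timeGrid", "BiasedRun", function(x) x@trajectory@times)

#' @rdname hldaKinetics-generics
#' @export
setMethod("latentX", "BiasedRun", function(x) x@trajectory@x)

#' @rdname hldaKinetics-generics
#' @export
setMethod("biasEnergy", "BiasedRun", function(x) x@biasEnergy)

#' @rdname hldaKinetics-generics
#' @export
setMethod("accelFactor", "BiasedRun", function(x) x@accelFactor)

#' @rdname hldaKinetics-generics
#' @export
setMethod("accelFactor", "FPTRecord", function(x) x@accelFactor)

#' @rdname hldaKinetics-generics
#' @export
setMethod("mfpt", "MFPTEstimate", function(x) x@mfpt)

#' @rdname hldaKinetics-generics
#' @export
setMethod("rateConstant", "MFPTEstimate", function(x) x@rate)

#' Coerce a StateLabels object to the bare label factor
#' @param x a [StateLabels-class].
#' @return factor of per-frame labels.
#' @export
stateAssignments <- function(x) {
  stopifnot(is(x, "StateLabels"))
  x@labels
}

#' State thresholds of a StateLabels object
#' @param x a [StateLabels-class].
#' @return named numeric vector \code{c(tF = , tU = )}.
#' @export
stateThresholds <- function(x) {
  stopifnot(is(x, "StateLabels"))
  c(tF = x@tF, tU = x@tU)
}

#' Turn a ResidueImportanceProfile into a data.frame
#' @param x a [ResidueImportanceProfile-class].
#' @param row.names,optional,... ignored (S3 consistency).
#' @return data.frame with residue, nPairs, score, normalizedScore.
#' @export
as.data.frame.ResidueImportanceProfile <- function(x, row.names = NULL,
                                                   optional = FALSE, ...) {
  data.frame(residue = x@residues, nPairs = x@nPairs, score = x@score,
             normalizedScore = x@normalizedScore)
}

#' Screening table of a ScreeningReport
#' @param x a [ScreeningReport-class].
#' @param row.names,optional,... ignored (S3 consistency).
#' @export
as.data.frame.ScreeningReport <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  x@table
}

setMethod("show", "TwoStateToySpec", function(object) {
  cat("TwoStateToySpec\n")
  cat(sprintf("  barrier dU = %.3g kT, minima at +/- %.3g, gamma = %.3g, kT = %.3g\n",
              object@barrierHeight, object@wellSeparation, object@friction,
              object@kT))
  cat(sprintf("  %d residues, %d descriptor pairs (|b| in [%.3g, %.3g], sigma in [%.3g, %.3g])\n",
              object@nResidues, nrow(object@pairs),
              min(abs(object@loadings)), max(abs(object@loadings)),
              min(object@noiseSD), max(object@noiseSD)))
})

setMethod("show", "LatentTrajectory", function(object) {
  n <- length(object@x)
  cat(sprintf("LatentTrajectory: %d frames, t in [0, %.4g], dt = %.4g, seed %d\n",
              n, if (n) object@times[n] else 0, object@dt, object@seed))
})

setMethod("show", "BiasedRun", function(object) {
  cat(sprintf("BiasedRun: %d frames, %d hills, %s\n",
              length(object@trajectory@x), nrow(object@hills),
              if (object@crossed)
                sprintf("crossed at tau = %.4g (alpha = %.3g, t* = %.4g)",
                        object@biasedFPT, object@accelFactor,
                        object@rescaledFPT)
              else "not crossed"))
})

setMethod("show", "StateLabels", function(object) {
  tab <- table(object@labels)
  cat(sprintf("StateLabels: %d frames (tF = %.3g, tU = %.3g)\n",
              length(object@labels), object@tF, object@tU))
  cat(sprintf("  folded %d | excluded %d | unfolded %d\n",
              tab[["folded"]], tab[["excluded"]], tab[["unfolded"]]))
})

setMethod("show", "StateStats", function(object) {
  cat(sprintf("StateStats [%s]: n = %d, %d descriptors%s\n", object@state,
              object@n, length(object@mu),
              if (object@regularized) " (ridge-regularized)" else ""))
})

setMethod("show", "HLDAModel", function(object) {
  cat("HLDAModel (two-state harmonic LDA)\n")
  if (object@noSeparation) {
    cat("  flagged: no separation (lambda below tolerance)\n")
    return(invisible(NULL))
  }
  cat(sprintf("  lambda = %.6g over %d descriptors; %s\n", object@lambda,
              length(object@weights), object@signConvention))
  w <- sort(abs(object@weights), decreasing = TRUE)
  k <- min(3L, length(w))
  cat("  top |W|: ", paste(sprintf("%s = %.3g", names(w)[seq_len(k)],
                                   w[seq_len(k)]), collapse = ", "), "\n")
})

setMethod("show", "ResidueImportanceProfile", function(object) {
  cat(sprintf("ResidueImportanceProfile: %d residues%s\n",
              length(object@residues),
              if (object@allZero) " (all weights zero; unnormalized)" else ""))
  df <- as.data.frame(object)
  print(utils::head(df[order(-df$score), ], 5L), row.names = FALSE)
})

setMethod("show", "FPTRecord", function(object) {
  if (object@crossed)
    cat(sprintf("FPTRecord: tau = %.4g, alpha = %.4g, t* = %.4g\n",
                object@biasedFPT, object@accelFactor, object@rescaledFPT))
  else cat("FPTRecord: not crossed\n")
})

setMethod("show", "MFPTEstimate", function(object) {
  cat(sprintf("MFPTEstimate: k = %.4g, MFPT = %.4g (R^2 = %.4f at m = %d of %d crossed / %d total)\n",
              object@rate, object@mfpt, object@r2, object@mSelected,
              object@nCrossed, object@nTotal))
  cat(sprintf("  censored-MLE cross-check: k = %.4g\n", object@kMLE))
})

setMethod("show", "ScreeningReport", function(object) {
  cat(sprintf("ScreeningReport vs %s (lambda_ref = %.4g, neutral band +/- %.0f%%)\n",
              object@referenceId, object@referenceLambda,
              100 * object@tolerance))
  print(object@table, row.names = FALSE)
})
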