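## Pairwise-distance descriptor matrix and Spearman-correlation pruning.

#' Build a DescriptorMatrix
#'
#' @param values frames x descriptors numeric matrix.
#' @param pairs pair table with columns \code{p}, \code{q}, \code{label}
#'   (see [pairTable()]); one row per descriptor column.
#' @param state optional per-frame state label.
#' @return a [DescriptorMatrix-class].
#' @export
DescriptorMatrix <- function(values, pairs, state = NULL) {
  values <- as.matrix(values)
  if (nrow(pairs) != ncol(values))
    stop("pair table rows (", nrow(pairs), ") must match descriptor columns (",
         ncol(values), ")")
  assays <- S4Vectors::SimpleList(distances = unname(t(values)))
  rd <- S4Vectors::DataFrame(p = as.integer(pairs$p), q = as.integer(pairs$q),
                             row.names = pairs$label)
  cd <- if (is.null(state)) {
    S4Vectors::DataFrame(row.names = sprintf("frame_%d", seq_len(nrow(values))))
  } else {
    stopifnot(length(state) == nrow(values))
    S4Vectors::DataFrame(state = as.character(state),
                         row.names = sprintf("frame_%d", seq_len(nrow(values))))
  }
  se <- SummarizedExperiment(assays = assays, rowData = rd, colData = cd)
  new("DescriptorMatrix", se)
}

# pair table (p, q, label) of a DescriptorMatrix
.pairsOf <- function(x) {
  rd <- rowData(x)
  data.frame(p = rd$p, q = rd$q, label = rownames(x), stringsAsFactors = FALSE)
}

#' Compute pairwise residue-distance descriptors from coordinates
#'
#' One column per residue pair \eqn{(p, q)}, \eqn{p < q},
#' \eqn{|p - q| \ge} \code{minSeparation}: the Euclidean distance between
#' the residues' representative atoms (C-alpha for real structures) in each
#' frame.
#'
#' @param frames frames x residues x 3 coordinate array; rows of the second
#'   dimension are residues in sequence order. Any residue with missing
#'   (non-finite) coordinates in any frame triggers an error naming it.
#' @param minSeparation minimum sequence separation (default 2: adjacent
#'   backbone distances are nearly constant and ill-condition the state
#'   covariances).
#' @param state optional per-frame state label carried into the result.
#' @return a [DescriptorMatrix-class].
#' @examples
#' fr <- array(0, c(1, 3, 3)); fr[1, , 1] <- c(0, 1, 2)
#' descriptorValues(computePairDistances(fr, minSeparation = 1))
#' @export
computePairDistances <- function(frames, minSeparation = 2L, state = NULL) {
  stopifnot(length(dim(frames)) == 3L, dim(frames)[3L] == 3L)
  nres <- dim(frames)[2L]
  bad <- which(apply(frames, 2L, function(z) any(!is.finite(z))))
  if (length(bad))
    stop("missing coordinates for residue(s): ", paste(bad, collapse = ", "))
  pairs <- pairTable(nres, minSeparation)
  vals <- vapply(seq_len(nrow(pairs)), function(k) {
    d <- frames[, pairs$p[k], , drop = FALSE] -
         frames[, pairs$q[k], , drop = FALSE]
    sqrt(rowSums(matrix(d, dim(frames)[1L], 3L)^2))
  }, numeric(dim(frames)[1L]))
  vals <- matrix(vals, nrow = dim(frames)[1L])
  colnames(vals) <- pairs$label
  DescriptorMatrix(vals, pairs = pairs, state = state)
}

#' Prune redundant descriptors by iterative Spearman filtering
#'
#' Repeatedly locates the worst-offending descriptor pair (largest absolute
#' Spearman correlation above the cutoff) and discards the member with the
#' larger mean \eqn{|\rho|} to all other remaining descriptors (ties broken
#' by lexicographic pair label: the later label is dropped), until no pair
#' of kept columns has \eqn{|\rho| >} cutoff. Constant (zero-variance)
#' columns are dropped first with a warning. The postcondition is audited
#' on every run. The result is invariant to column permutation of the
#' input.
#'
#' @param x a [DescriptorMatrix-class] with \eqn{\ge 2} frames.
#' @param cutoff correlation cutoff in (0, 1]; default 0.93.
#' @return a list with elements \code{matrix} (the pruned
#'   [DescriptorMatrix-class]) and \code{report} (a data.frame accounting
#'   for every column: label, kept flag, partner label and \eqn{\rho} at
#'   removal; the cutoff is attached as attribute \code{cutoff}).
#' @export
pruneDescriptors <- function(x, cutoff = 0.93) {
  stopifnot(is(x, "DescriptorMatrix"))
  if (!(cutoff > 0 && cutoff <= 1)) stop("cutoff must be in (0, 1]")
  v <- descriptorValues(x)
  if (nrow(v) < 2L) stop("need >= 2 frames to estimate correlations")
  labels <- colnames(v)
  dropped <- character(0)
  partner <- character(0)
  rhoAt <- numeric(0)
  # constant columns go first
  isConst <- apply(v, 2L, function(z) sd(z) == 0)
  if (any(isConst)) {
    warning("dropping constant descriptor(s): ",
            paste(labels[isConst], collapse = ", "))
    dropped <- labels[isConst]
    partner <- rep(NA_character_, sum(isConst))
    rhoAt <- rep(NA_real_, sum(isConst))
    v <- v[, !isConst, drop = FALSE]
  }
  repeat {
    if (ncol(v) < 2L) break
    rho <- abs(cor(v, method = "spearman"))
    diag(rho) <- 0
    worst <- max(rho)
    if (worst <= cutoff) break
    idx <- which(rho == worst, arr.ind = TRUE)[1L, ]
    cand <- colnames(v)[idx]
    meanRho <- rowMeans(rho[cand, , drop = FALSE]) * ncol(v) / (ncol(v) - 1)
    drop <- if (abs(diff(meanRho)) > 1e-12) cand[which.max(meanRho)]
            else sort(cand)[2L]   # tie: drop the lexicographically later
    keep0 <- setdiff(cand, drop)
    dropped <- c(dropped, drop)
    partner <- c(partner, keep0)
    rhoAt <- c(rhoAt, worst)
    v <- v[, setdiff(colnames(v), drop), drop = FALSE]
  }
  keptLabels <- colnames(v)
  # postcondition audit
  if (ncol(v) >= 2L) {
    rho <- abs(cor(v, method = "spearman"))
    diag(rho) <- 0
    stopifnot(max(rho) <= cutoff + 1e-12)
  }
  pairs <- .pairsOf(x)
  keepIdx <- match(keptLabels, pairs$label)
  pruned <- DescriptorMatrix(descriptorValues(x)[, keptLabels, drop = FALSE],
                             pairs = pairs[keepIdx, , drop = FALSE],
                             state = frameStates(x))
  report <- rbind(
    data.frame(label = keptLabels, kept = TRUE, partner = NA_character_,
               rho = NA_real_, stringsAsFactors = FALSE),
    if (length(dropped))
      data.frame(label = dropped, kept = FALSE, partner = partner,
                 rho = rhoAt, stringsAsFactors = FALSE)
  )
  report <- report[order(match(report$label, labels)), ]
  rownames(report) <- NULL
  attr(report, "cutoff") <- cutoff
  stopifnot(setequal(report$label, labels))
  list(matrix = pruned, report = report)
}
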