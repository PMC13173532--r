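## Residue-level importance: aggregate pairwise CV weights by residue,
## rank kinetic hot spots, and screen mutants by their eigenvalues.

#' Per-residue kinetic importance scores
#'
#' \eqn{I_r = \frac{1}{|N_r|} \sum_{q \in N_r} |W_{rq}|}: the mean absolute
#' CV weight over the kept descriptor pairs involving residue \eqn{r}.
#' Large \eqn{I_r} marks residues whose perturbation is most likely to
#' change the folded/unfolded separation, i.e. kinetic hot spots. The
#' average runs over kept (post-pruning) pairs, since those define
#' \eqn{W}; residues present in \code{residues} but absent from every kept
#' pair are reported as unscored (NA) rather than zero.
#'
#' @param model an [HLDAModel-class] whose pair labels parse as residue
#'   pairs.
#' @param residues residue index universe to report; default: the residues
#'   occurring in the model's kept pairs.
#' @return a [ResidueImportanceProfile-class]. When every weight is zero
#'   the normalization is skipped and the profile is flagged.
#' @examples
#' # three residues, pairs (1,2), (1,3), (2,3), W = (0.6, -0.2, 0.1)
#' s <- c(d_1_2 = 0.6, d_1_3 = -0.2, d_2_3 = 0.1)
#' @export
residueImportance <- function(model, residues = NULL) {
  stopifnot(is(model, "HLDAModel"))
  pr <- model@pairs
  if (any(is.na(pr$q)))
    stop("model pair labels do not parse as residue pairs")
  if (is.null(residues)) residues <- sort(unique(c(pr$p, pr$q)))
  residues <- as.integer(residues)
  aw <- abs(model@weights)
  score <- vapply(residues, function(r) {
    touch <- pr$p == r | pr$q == r
    if (!any(touch)) NA_real_ else mean(aw[touch])
  }, numeric(1))
  nPairs <- vapply(residues, function(r) sum(pr$p == r | pr$q == r),
                   integer(1))
  allZero <- all(is.na(score)) || max(score, na.rm = TRUE) == 0
  norm <- if (allZero) score else score / max(score, na.rm = TRUE)
  new("ResidueImportanceProfile", residues = residues, score = score,
      normalizedScore = norm, nPairs = nPairs, allZero = allZero)
}

#' Rank residues as kinetic hot spots
#'
#' Residues sorted by \eqn{I_r} descending; ties broken by residue index
#' ascending. Unscored residues are omitted.
#'
#' @param profile a [ResidueImportanceProfile-class].
#' @param topK number of residues to return; a value beyond the residue
#'   count returns the full ranking.
#' @return integer vector of residue indices, most important first.
#' @export
rankHotspots <- function(profile, topK = Inf) {
  stopifnot(is(profile, "ResidueImportanceProfile"))
  ok <- !is.na(profile@score)
  ord <- order(-profile@score[ok], profile@residues[ok])
  ranked <- profile@residues[ok][ord]
  ranked[seq_len(min(topK, length(ranked)))]
}

#' Screen mutants by their HLDA eigenvalues
#'
#' One row per mutant comparing its eigenvalue to the reference:
#' direction = \code{slower} when
#' \eqn{\lambda_{mut} > \lambda_{ref}(1 + tol)} (greater separation,
#' higher barrier), \code{faster} when
#' \eqn{\lambda_{mut} < \lambda_{ref}(1 - tol)}, otherwise
#' \code{neutral}. Mutants flagged "no separation" are marked unreliable.
#'
#' @param reference the reference [HLDAModel-class].
#' @param mutants named list of mutant [HLDAModel-class] objects (an empty
#'   list yields a header-only report).
#' @param tolerance relative half-width of the neutral band (default 0.05).
#' @param referenceProfile optional [ResidueImportanceProfile-class] of the
#'   reference, used to annotate mutated sites.
#' @param mutatedResidues optional named integer vector (same names as
#'   \code{mutants}) giving the mutated residue of each mutant.
#' @param referenceId identifier used in the report (default "reference").
#' @return a [ScreeningReport-class].
#' @export
screenMutants <- function(reference, mutants, tolerance = 0.05,
                          referenceProfile = NULL, mutatedResidues = NULL,
                          referenceId = "reference") {
  stopifnot(is(reference, "HLDAModel"), is.list(mutants), tolerance >= 0)
  if (length(mutants) && is.null(names(mutants)))
    names(mutants) <- sprintf("mutant_%d", seq_along(mutants))
  lref <- reference@lambda
  rows <- lapply(names(mutants), function(id) {
    m <- mutants[[id]]
    stopifnot(is(m, "HLDAModel"))
    lam <- m@lambda
    dir <- if (lam > lref * (1 + tolerance)) "slower"
           else if (lam < lref * (1 - tolerance)) "faster" else "neutral"
    res <- if (!is.null(mutatedResidues) && id %in% names(mutatedResidues))
      as.integer(mutatedResidues[[id]]) else NA_integer_
    ir <- if (!is.na(res) && !is.null(referenceProfile)) {
      i <- match(res, referenceProfile@residues)
      if (is.na(i)) NA_real_ else referenceProfile@score[i]
    } else NA_real_
    data.frame(mutant = id, lambda = lam, direction = dir,
               reliable = !m@noSeparation, mutatedResidue = res,
               referenceIr = ir, stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows)
         else data.frame(mutant = character(0), lambda = numeric(0),
                         direction = character(0), reliable = logical(0),
                         mutatedResidue = integer(0),
                         referenceIr = numeric(0), stringsAsFactors = FALSE)
  new("ScreeningReport", table = tab, referenceId = referenceId,
      referenceLambda = lref, tolerance = tolerance)
}
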