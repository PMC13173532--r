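#' Enumerate residue-pair descriptor labels
#'
#' Builds the table of residue pairs \eqn{(p, q)}, \eqn{p < q}, with
#' \eqn{|p - q| \ge} \code{minSeparation}, in the lexicographic order used
#' throughout the package. Labels follow the \code{"d_p_q"} convention.
#'
#' @param nResidues number of residues.
#' @param minSeparation minimum sequence separation \eqn{|p - q|} for a pair
#'   to be included. Adjacent backbone distances are nearly constant and
#'   ill-condition the state covariances, hence the default of 2.
#' @return a \code{data.frame} with integer columns \code{p}, \code{q} and a
#'   character column \code{label}.
#' @examples
#' nrow(pairTable(10, minSeparation = 2))  # 36 pairs
#' @export
pairTable <- function(nResidues, minSeparation = 2L) {
  nResidues <- as.integer(nResidues)
  stopifnot(nResidues >= 2L, minSeparation >= 1L)
  cmb <- utils::combn(nResidues, 2L)
  keep <- (cmb[2L, ] - cmb[1L, ]) >= minSeparation
  if (!any(keep))
    stop("no residue pair satisfies minSeparation = ", minSeparation)
  data.frame(
    p = cmb[1L, keep],
    q = cmb[2L, keep],
    label = paste0("d_", cmb[1L, keep], "_", cmb[2L, keep]),
    stringsAsFactors = FALSE
  )
}

#' Parse "d_p_q" pair labels back into residue indices
#'
#' @param labels character vector of labels of the form \code{"d_p_q"}.
#' @return a \code{data.frame} with columns \code{p}, \code{q}, \code{label}.
#' @export
parsePairLabels <- function(labels) {
  m <- regmatches(labels, regexec("^d_([0-9]+)_([0-9]+)$", labels))
  bad <- lengths(m) != 3L
  if (any(bad))
    stop("malformed pair label(s): ", paste(labels[bad], collapse = ", "))
  data.frame(
    p = as.integer(vapply(m, `[`, "", 2L)),
    q = as.integer(vapply(m, `[`, "", 3L)),
    label = as.character(labels),
    stringsAsFactors = FALSE
  )
}

# shared validity helper: finite numeric vector
.allFinite <- function(x) is.numeric(x) && all(is.finite(x))
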