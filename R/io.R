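## Plain-text readers and writers: descriptor matrices and pruning reports
## (TSV), HLDA models (YAML), bias logs and FPT records (TSV), multi-model
## PDB (via bio3d) and XYZ coordinate stacks.

#' Write / read a descriptor matrix as delimited text
#'
#' Tab-separated, one row per frame, header row = pair labels
#' (\code{d_p_q}); a leading \code{state} column is included when frame
#' states are set.
#'
#' @param x a [DescriptorMatrix-class].
#' @param path file path.
#' @return \code{writeDescriptorMatrix}: the path, invisibly;
#'   \code{readDescriptorMatrix}: a [DescriptorMatrix-class].
#' @export
writeDescriptorMatrix <- function(x, path) {
  stopifnot(is(x, "DescriptorMatrix"))
  df <- as.data.frame(descriptorValues(x), check.names = FALSE)
  st <- frameStates(x)
  if (!is.null(st)) df <- cbind(state = st, df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDescriptorMatrix
#' @export
readDescriptorMatrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  state <- NULL
  if ("state" %in% names(df)) {
    state <- df$state
    df$state <- NULL
  }
  DescriptorMatrix(as.matrix(df), pairs = parsePairLabels(names(df)),
                   state = state)
}

#' Write / read a pruning report
#'
#' @param report the report data.frame from [pruneDescriptors()].
#' @param path file path.
#' @export
writePruningReport <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cutoff\t%.10g", attr(report, "cutoff")), con)
  write.table(report, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePruningReport
#' @export
readPruningReport <- function(path) {
  first <- readLines(path, n = 1L)
  report <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                       stringsAsFactors = FALSE)
  attr(report, "cutoff") <- as.numeric(strsplit(first, "\t")[[1L]][2L])
  report
}

#' Serialize / restore an HLDA model as structured text (YAML)
#'
#' Stores the pair labels, weights, eigenvalue, state means, scatter
#' matrices, sign convention and flags; the round trip reproduces the
#' model to numerical precision.
#'
#' @param model an [HLDAModel-class].
#' @param path file path.
#' @export
writeHLDAModel <- function(model, path) {
  stopifnot(is(model, "HLDAModel"))
  obj <- list(
    pair_labels = model@pairs$label,
    weights = unname(model@weights),
    lambda = model@lambda,
    mu_folded = unname(model@muF),
    mu_unfolded = unname(model@muU),
    global_mean = unname(model@globalMean),
    Sw = apply(model@Sw, 1L, as.numeric, simplify = FALSE),
    Sb = apply(model@Sb, 1L, as.numeric, simplify = FALSE),
    sign_convention = model@signConvention,
    no_separation = model@noSeparation
  )
  writeLines(yaml::as.yaml(obj, precision = 15L), path)
  invisible(path)
}

#' @rdname writeHLDAModel
#' @export
readHLDAModel <- function(path) {
  obj <- yaml::read_yaml(path)
  p <- length(obj$pair_labels)
  toMat <- function(rows) do.call(rbind, lapply(rows, as.numeric))
  w <- setNames(as.numeric(obj$weights), obj$pair_labels)
  mu <- function(v) setNames(as.numeric(v), obj$pair_labels)
  new("HLDAModel", weights = w, lambda = as.numeric(obj$lambda),
      Sw = toMat(obj$Sw), Sb = toMat(obj$Sb), muF = mu(obj$mu_folded),
      muU = mu(obj$mu_unfolded), globalMean = mu(obj$global_mean),
      pairs = parsePairLabels(obj$pair_labels),
      signConvention = obj$sign_convention,
      noSeparation = isTRUE(obj$no_separation))
}

#' Write / read a bias log (time, CV value, bias energy in kT)
#'
#' @param run a [BiasedRun-class].
#' @param path file path.
#' @export
writeBiasLog <- function(run, path) {
  stopifnot(is(run, "BiasedRun"))
  df <- data.frame(time = timeGrid(run), s = run@cv, V = biasEnergy(run))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBiasLog
#' @export
readBiasLog <- function(path) {
  read.table(path, header = TRUE, sep = "\t")
}

#' Write / read first-passage records
#'
#' @param records data.frame as from [fptRecords()].
#' @param path file path.
#' @export
writeFPTRecords <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFPTRecords
#' @export
readFPTRecords <- function(path) {
  read.table(path, header = TRUE, sep = "\t")
}

#' Read representative-atom coordinates from a (multi-model) PDB file
#'
#' Uses \pkg{bio3d} to parse the file and extracts one representative atom
#' per residue: C-alpha by default, or the full N/CA/C/O backbone centroid
#' when \code{atoms = "backbone"} (which backbone atoms define a residue's
#' position is a modelling choice; C-alpha is the minimal common one).
#'
#' @param path PDB file path.
#' @param atoms \code{"calpha"} (default) or \code{"backbone"}.
#' @return a frames x residues x 3 array.
#' @export
readPDBFrames <- function(path, atoms = c("calpha", "backbone")) {
  atoms <- match.arg(atoms)
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  resIds <- unique(paste(pdb$atom$chain, pdb$atom$resno))
  if (atoms == "calpha") {
    sel <- which(pdb$atom$elety == "CA")
    selRes <- paste(pdb$atom$chain, pdb$atom$resno)[sel]
    missing <- setdiff(resIds, selRes)
    if (length(missing))
      stop("missing C-alpha for residue(s): ", paste(missing, collapse = ", "))
    idx <- sel[match(resIds, selRes)]
    xyz <- pdb$xyz[, as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx)),
                   drop = FALSE]
    nres <- length(idx)
    arr <- array(NA_real_, c(nrow(xyz), nres, 3L))
    for (f in seq_len(nrow(xyz)))
      arr[f, , ] <- matrix(xyz[f, ], nres, 3L, byrow = TRUE)
    arr
  } else {
    bb <- c("N", "CA", "C", "O")
    nres <- length(resIds)
    arr <- array(NA_real_, c(nrow(pdb$xyz), nres, 3L))
    for (r in seq_len(nres)) {
      sel <- which(paste(pdb$atom$chain, pdb$atom$resno) == resIds[r] &
                     pdb$atom$elety %in% bb)
      if (!length(sel))
        stop("missing backbone atoms for residue ", resIds[r])
      cols <- as.vector(rbind(3 * sel - 2, 3 * sel - 1, 3 * sel))
      for (f in seq_len(nrow(pdb$xyz))) {
        m <- matrix(pdb$xyz[f, cols], length(sel), 3L, byrow = TRUE)
        arr[f, r, ] <- colMeans(m)
      }
    }
    arr
  }
}

#' Write a coordinate stack as a multi-model PDB of C-alpha pseudo-atoms
#'
#' @param frames frames x atoms x 3 array.
#' @param path output path.
#' @export
writePDBFrames <- function(frames, path) {
  stopifnot(length(dim(frames)) == 3L)
  nat <- dim(frames)[2L]
  xyz <- t(apply(frames, 1L, function(m) as.vector(t(m))))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = seq_len(nat), resid = rep("GLY", nat),
                   elety = rep("CA", nat))
  invisible(path)
}

#' Read / write an XYZ coordinate stack
#'
#' Plain-text XYZ trajectory: per frame an atom-count line, a comment
#' line, then \code{element x y z} records.
#'
#' @param frames frames x atoms x 3 array.
#' @param path file path.
#' @param element element symbol to write (default "C").
#' @export
writeXYZFrames <- function(frames, path, element = "C") {
  stopifnot(length(dim(frames)) == 3L)
  con <- file(path, "w")
  on.exit(close(con))
  nat <- dim(frames)[2L]
  for (f in seq_len(dim(frames)[1L])) {
    writeLines(c(as.character(nat), sprintf("frame %d", f)), con)
    writeLines(sprintf("%s %.8f %.8f %.8f", element, frames[f, , 1L],
                       frames[f, , 2L], frames[f, , 3L]), con)
  }
  invisible(path)
}

#' @rdname writeXYZFrames
#' @export
readXYZFrames <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    nat <- as.integer(trimws(lines[i]))
    if (is.na(nat)) stop("malformed XYZ file at line ", i)
    block <- lines[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    m <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- m
    i <- i + 2L + nat
  }
  nat <- nrow(frames[[1L]])
  arr <- array(NA_real_, c(length(frames), nat, 3L))
  for (f in seq_along(frames)) arr[f, , ] <- frames[[f]]
  arr
}

#' Write a residue-importance profile or screening report as TSV
#'
#' @param x a [ResidueImportanceProfile-class] or [ScreeningReport-class].
#' @param path file path.
#' @export
writeReportTSV <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
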