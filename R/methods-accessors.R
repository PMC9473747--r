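#' @rdname PeptideSystem-class
setMethod("nChains", "PeptideSystem", function(x) length(x@chains))

#' @rdname PeptideSystem-class
setMethod("nAtoms", "PeptideSystem", function(x) nrow(x@atoms))

#' @rdname PeptideSystem-class
setMethod("peptideSequence", "PeptideSystem", function(x) x@sequence)

#' @rdname PeptideSystem-class
setMethod("atomData", "PeptideSystem", function(x) x@atoms)

#' @rdname PeptideTrajectory-class
setMethod("nFrames", "PeptideTrajectory", function(x) dim(x@coords)[3])

#' @rdname PeptideTrajectory-class
setMethod("nChains", "PeptideTrajectory", function(x) nChains(x@system))

#' @rdname PeptideTrajectory-class
setMethod("nAtoms", "PeptideTrajectory", function(x) nAtoms(x@system))

#' @rdname PeptideTrajectory-class
setMethod("peptideSequence", "PeptideTrajectory",
          function(x) x@system@sequence)

#' @rdname PeptideTrajectory-class
setMethod("getFrame", "PeptideTrajectory", function(x, i) {
  stopifnot(length(i) == 1L, i >= 1L, i <= nFrames(x))
  m <- x@coords[, , i, drop = FALSE]
  dim(m) <- dim(x@coords)[1:2]
  colnames(m) <- c("x", "y", "z")
  m
})

#' @rdname PeptideTrajectory-class
setMethod("frameTimes", "PeptideTrajectory", function(x) x@times)

#' @rdname PeptideTrajectory-class
#' @param system accessor for the underlying [PeptideSystem-class].
#' @export
trajectorySystem <- function(x) {
  stopifnot(is(x, "PeptideTrajectory"))
  x@system
}

#' @rdname SSAssignment-class
setMethod("ssCodes", "SSAssignment", function(x) x@codes)

#' @rdname SSAssignment-class
#' @export
ssResidues <- function(x) {
  stopifnot(is(x, "SSAssignment"))
  x@residues
}

#' @rdname SSAssignment-class
#' @export
ssBridges <- function(x) {
  stopifnot(is(x, "SSAssignment"))
  x@bridges
}

#' @rdname ClusterResult-class
setMethod("clusterCenters", "ClusterResult", function(x) x@centers)

#' @rdname ClusterResult-class
setMethod("clusterMembers", "ClusterResult", function(x) x@members)

#' @rdname ClusterResult-class
setMethod("clusterPopulations", "ClusterResult", function(x) x@populations)

#' @rdname Landscape-class
setMethod("pmfMatrix", "Landscape", function(x) x@pmf)

#' @rdname Landscape-class
setMethod("probabilityMatrix", "Landscape", function(x) x@H)

#' @rdname OligomerClass-class
setMethod("oligomerLabel", "OligomerClass", function(x) x@label)

#' @rdname OligomerClass-class
setMethod("strandCounts", "OligomerClass", function(x) x@strandCounts)

#' @rdname OligomerClass-class
#' @export
mixedOrientation <- function(x) {
  stopifnot(is(x, "OligomerClass"))
  x@mixed
}

#' @rdname SheetGraph-class
#' @export
sheetStrands <- function(x) {
  stopifnot(is(x, "SheetGraph"))
  x@strands
}

#' @rdname SheetGraph-class
#' @export
sheetEdges <- function(x) {
  stopifnot(is(x, "SheetGraph"))
  x@edges
}

setMethod("show", "PeptideSystem", function(object) {
  cat(sprintf("PeptideSystem: %d chain(s) of '%s' (residues %d-%d), %d atoms\n",
              nChains(object), object@sequence, object@offset,
              object@offset + nchar(object@sequence) - 1L, nAtoms(object)))
  invisible(NULL)
})

setMethod("show", "PeptideTrajectory", function(object) {
  tm <- if (length(object@times))
    sprintf(", t = %.4g..%.4g ns", object@times[1],
            object@times[length(object@times)])
  else ""
  cat(sprintf("PeptideTrajectory: %d frame(s)%s\n", nFrames(object), tm))
  show(object@system)
  invisible(NULL)
})

setMethod("show", "SSAssignment", function(object) {
  cat(sprintf("SSAssignment: %d residue(s) x %d frame(s)\n",
              nrow(object@codes), ncol(object@codes)))
  tab <- table(factor(object@codes,
                      levels = c("H", "G", "I", "E", "B", "T", "S", "-")))
  cat("  code counts:",
      paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  invisible(NULL)
})

setMethod("show", "SheetGraph", function(object) {
  cat(sprintf("SheetGraph: %d strand(s), %d pairing(s)\n",
              nrow(object@strands), nrow(object@edges)))
  invisible(NULL)
})

setMethod("show", "OligomerClass", function(object) {
  cnt <- if (length(object@strandCounts))
    paste0(" [", paste(object@strandCounts, collapse = "+"), "]")
  else ""
  cat(sprintf("OligomerClass: %s%s%s\n", object@label, cnt,
              if (object@mixed) " (mixed orientation)" else ""))
  invisible(NULL)
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: %d cluster(s), cutoff %.2f Angstrom\n",
              length(object@centers), object@cutoff))
  k <- min(4L, length(object@centers))
  if (k) {
    for (i in seq_len(k))
      cat(sprintf("  cluster %d: center frame %d, %d member(s), %.1f%%\n",
                  i, object@centers[i], length(object@members[[i]]),
                  100 * object@populations[i]))
  }
  invisible(NULL)
})

setMethod("show", "Landscape", function(object) {
  occ <- is.finite(object@pmf)
  cat(sprintf(
    "Landscape: %d x %d bins, %d occupied, T = %g K, max PMF %.3f kJ/mol\n",
    nrow(object@H), ncol(object@H), sum(occ), object@temperature,
    if (any(occ)) max(object@pmf[occ]) else NA_real_))
  invisible(NULL)
})

setMethod("show", "AnalysisParameters", function(object) {
  cat("AnalysisParameters:\n")
  cat(sprintf("  H-bond: N-O <= %.2f Angstrom, N-H...O >= %g deg\n",
              object@hbondMaxDist, object@hbondMinAngle))
  cat(sprintf("  contact: heavy-atom distance <= %.2f Angstrom, |i-j| >= %d\n",
              object@contactMaxDist, object@minSeqSeparation))
  cat(sprintf("  sheet: run >= %d residues, >= %d backbone H-bonds\n",
              object@sheetMinRun, object@sheetMinHBonds))
  cat(sprintf("  clustering cutoff: %.2f Angstrom; T = %g K\n",
              object@clusterCutoff, object@temperature))
  invisible(NULL)
})

#' Construct analysis parameters
#'
#' @param ... named parameter overrides; see [AnalysisParameters-class]
#'   for slot names, units and defaults.
#' @return an [AnalysisParameters-class] object.
#' @examples
#' analysisParameters(contactMaxDist = 6.0)
#' @export
analysisParameters <- function(...) {
  args <- list(...)
  intslots <- c("minSeqSeparation", "sheetMinRun", "sheetMinHBonds")
  for (nm in intersect(names(args), intslots))
    args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("AnalysisParameters"), args))
}
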