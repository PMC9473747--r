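#' Construct a peptide system
#'
#' @param sequence one-letter amino-acid string of one chain.
#' @param atoms `data.frame` with columns `name`, `element`, `chain`,
#'   `resno` (one row per atom, file order).  `element` may be omitted and
#'   is then derived from the atom name.
#' @param offset residue number of the first residue (105 for the
#'   transthyretin fragment TTR(105-115)).
#' @return a [PeptideSystem-class].
#' @export
peptideSystem <- function(sequence, atoms, offset = 105L) {
  if (is.null(atoms$element))
    atoms$element <- .element_from_name(atoms$name)
  chains <- unique(atoms$chain)
  new("PeptideSystem", sequence = sequence, chains = chains,
      atoms = as.data.frame(atoms), offset = as.integer(offset))
}

#' Construct a peptide trajectory
#'
#' @param system a [PeptideSystem-class].
#' @param coords an `n_atoms x 3 x n_frames` array, a single `n_atoms x 3`
#'   matrix, or a list of such matrices (Angstrom).
#' @param times optional frame times in ns (strictly increasing).
#' @return a [PeptideTrajectory-class].
#' @export
peptideTrajectory <- function(system, coords, times = numeric(0)) {
  if (is.list(coords))
    coords <- array(unlist(coords), dim = c(nrow(coords[[1]]), 3,
                                            length(coords)))
  if (is.matrix(coords))
    coords <- array(coords, dim = c(nrow(coords), 3, 1))
  new("PeptideTrajectory", system = system, coords = coords,
      times = as.numeric(times))
}

#' Read a multi-model PDB file as a trajectory
#'
#' Reads a standard fixed-column PDB file with one `MODEL` per frame (or a
#' bare single structure) into a [PeptideTrajectory-class].  Coordinates are
#' kept in Angstrom as read; chain identifiers are preserved.  All `MODEL`
#' blocks must contain the same atoms.  Files with insertion codes are
#' rejected; for alternate locations the first location is kept.
#'
#' @param path path to a PDB file.
#' @param frameInterval optional time between frames, ns; when given, frame
#'   times `0, dt, 2 dt, ...` are attached.
#' @return a [PeptideTrajectory-class].
#' @examples
#' tr <- assembleState("sheet", nChains = 2, seed = 1)
#' f <- tempfile(fileext = ".pdb")
#' writeMultimodelPDB(tr, f)
#' readMultimodelPDB(f)
#' @export
readMultimodelPDB <- function(path, frameInterval = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  if (!any(is_atom)) stop("no ATOM records in ", path)

  # validate coordinate fields up front so malformed lines are reported
  # with their line number rather than surfacing as NA downstream
  atom_lines <- which(is_atom)
  xs <- suppressWarnings(as.numeric(substr(lines[atom_lines], 31, 38)))
  ys <- suppressWarnings(as.numeric(substr(lines[atom_lines], 39, 46)))
  zs <- suppressWarnings(as.numeric(substr(lines[atom_lines], 47, 54)))
  bad <- which(!is.finite(xs) | !is.finite(ys) | !is.finite(zs))
  if (length(bad))
    stop(sprintf("unparseable ATOM coordinates at line %d of %s",
                 atom_lines[bad[1]], path))

  # per-MODEL atom counts must agree
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) > 1L) {
    grp <- findInterval(atom_lines, model_starts)
    counts <- tabulate(grp, nbins = length(model_starts))
    if (length(unique(counts)) != 1L) {
      first_bad <- which(counts != counts[1])[1]
      stop(sprintf(
        "MODEL %d has %d atoms but MODEL 1 has %d in %s",
        first_bad, counts[first_bad], counts[1], path))
    }
  }

  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  if (any(!is.na(pdb$atom$insert)))
    stop("insertion codes are not supported: ", path)
  keep <- pdb$atom$type == "ATOM"
  if (!any(keep)) stop("no ATOM (peptide) records in ", path)

  at <- pdb$atom[keep, , drop = FALSE]
  chains <- unique(at$chain)
  seqs <- vapply(chains, function(ch) {
    sub <- at[at$chain == ch, ]
    res <- sub[!duplicated(sub$resno), ]
    paste(bio3d::aa321(res$resid[order(res$resno)]), collapse = "")
  }, character(1))
  if (length(unique(seqs)) != 1L)
    stop("all chains must share one peptide sequence; found: ",
         paste(unique(seqs), collapse = ", "))

  elesy <- at$elesy
  if (is.null(elesy) || all(is.na(elesy)) || all(elesy == ""))
    elesy <- .element_from_name(at$elety)
  elesy[is.na(elesy) | elesy == ""] <-
    .element_from_name(at$elety[is.na(elesy) | elesy == ""])

  system <- peptideSystem(
    sequence = seqs[[1]],
    atoms = data.frame(name = at$elety, element = toupper(trimws(elesy)),
                       chain = at$chain, resno = at$resno,
                       stringsAsFactors = FALSE),
    offset = min(at$resno)
  )

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nfr <- nrow(xyz)
  natom_all <- ncol(xyz) / 3
  idx3 <- rep((which(keep) - 1) * 3, each = 3) + rep(1:3, sum(keep))
  coords <- array(NA_real_, dim = c(sum(keep), 3, nfr))
  for (k in seq_len(nfr))
    coords[, , k] <- matrix(xyz[k, idx3], ncol = 3, byrow = TRUE)

  times <- if (is.finite(frameInterval))
    (seq_len(nfr) - 1) * frameInterval
  else numeric(0)
  peptideTrajectory(system, coords, times)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Emits standard fixed-column PDB with `MODEL`/`ENDMDL` per frame and `TER`
#' records between chains.  Coordinates exceeding the fixed column width
#' (|x| >= 10000 Angstrom) are rejected.
#'
#' @param traj a [PeptideTrajectory-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMultimodelPDB <- function(traj, path) {
  stopifnot(is(traj, "PeptideTrajectory"))
  if (nFrames(traj) < 1L) stop("trajectory has no frames")
  if (max(abs(traj@coords)) >= 1e4)
    stop("coordinate magnitude exceeds the PDB fixed column width")
  sys <- traj@system
  at <- sys@atoms
  rt <- .residue_table(sys)
  aa3 <- bio3d::aa123(rt$aa[.atom_residue_index(sys)])
  nfr <- nFrames(traj)
  xyz <- matrix(NA_real_, nrow = nfr, ncol = 3 * nrow(at))
  for (k in seq_len(nfr))
    xyz[k, ] <- as.vector(t(traj@coords[, , k]))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = at$resno, resid = aa3,
                   eleno = seq_len(nrow(at)), elety = at$name,
                   chain = at$chain, elesy = at$element,
                   chainter = TRUE, verbose = FALSE)
  invisible(path)
}

#' Select atoms of a peptide system
#'
#' Deterministic, order-preserving atom selections used by the analysis
#' operations.
#'
#' @param system a [PeptideSystem-class].
#' @param selection one of `"all"`, `"heavy"` (non-hydrogen), `"backbone"`
#'   (N, CA, C, O, plus OXT), `"calpha"`.
#' @param chain optional chain identifier(s) restricting the selection.
#' @return integer vector of atom indices (file order).
#' @examples
#' tr <- assembleState("helix", nChains = 1, seed = 1)
#' length(selectAtoms(trajectorySystem(tr), "calpha"))
#' @export
selectAtoms <- function(system, selection = c("all", "heavy", "backbone",
                                              "calpha"),
                        chain = NULL) {
  .stop_if_not_system(system)
  if (!is.character(selection) || length(selection) != 1L)
    stop("'selection' must be a single selector name")
  selection <- tolower(selection)
  at <- system@atoms
  keep <- switch(selection,
    all = rep(TRUE, nrow(at)),
    heavy = at$element != "H",
    backbone = at$name %in% c("N", "CA", "C", "O", "OXT"),
    calpha = at$name == "CA",
    stop("unknown selector: ", selection)
  )
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  which(keep)
}
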