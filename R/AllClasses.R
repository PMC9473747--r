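#' @import methods
NULL

#' Peptide system topology
#'
#' Immutable description of a multi-copy peptide system: the one-letter
#' sequence of the repeated peptide, the ordered chain identifiers, and the
#' per-atom metadata (atom name, element, residue number, chain).  Residue
#' numbers follow the biological numbering of the fragment; for the
#' transthyretin fragment TTR(105-115) the first residue is 105.
#'
#' @slot sequence one-letter amino-acid string of a single chain.
#' @slot chains ordered chain identifiers (all chains share `sequence`).
#' @slot atoms `data.frame` with columns `name`, `element`, `chain`,
#'   `resno` (one row per atom, file order).
#' @slot offset integer, residue number of the first residue (default 105).
#'
#' @exportClass PeptideSystem
setClass("PeptideSystem",
  representation(
    sequence = "character",
    chains = "character",
    atoms = "data.frame",
    offset = "integer"
  ),
  prototype(offset = 105L)
)

setValidity("PeptideSystem", function(object) {
  msg <- character()
  if (length(object@sequence) != 1L || nchar(object@sequence) < 1L)
    msg <- c(msg, "'sequence' must be a single non-empty string")
  need <- c("name", "element", "chain", "resno")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, sprintf("'atoms' must have columns %s",
                          paste(need, collapse = ", ")))
  else {
    nres <- nchar(object@sequence)
    lo <- object@offset
    hi <- object@offset + nres - 1L
    if (any(object@atoms$resno < lo | object@atoms$resno > hi))
      msg <- c(msg, "atom residue numbers fall outside the sequence")
    if (!setequal(unique(object@atoms$chain), object@chains))
      msg <- c(msg, "'chains' does not match the chains present in 'atoms'")
  }
  if (length(msg)) msg else TRUE
})

#' Trajectory of a peptide system
#'
#' Ordered coordinate frames bound to one [PeptideSystem-class].  Coordinates
#' are stored in Angstrom as an `n_atoms x 3 x n_frames` array; frame times
#' (ns) are optional (`numeric(0)` when absent).
#'
#' @slot system a [PeptideSystem-class].
#' @slot coords numeric array, `n_atoms x 3 x n_frames`, Angstrom.
#' @slot times numeric vector of frame times in ns, or `numeric(0)`.
#'
#' @exportClass PeptideTrajectory
setClass("PeptideTrajectory",
  representation(
    system = "PeptideSystem",
    coords = "array",
    times = "numeric"
  )
)

setValidity("PeptideTrajectory", function(object) {
  msg <- character()
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    msg <- c(msg, "'coords' must be an n_atoms x 3 x n_frames array")
  else {
    if (d[3] < 1L) msg <- c(msg, "trajectory must contain at least one frame")
    if (d[1] != nrow(object@system@atoms))
      msg <- c(msg, "coordinate count does not match system atom count")
    if (!all(is.finite(object@coords)))
      msg <- c(msg, "all coordinates must be finite")
    nt <- length(object@times)
    if (nt && nt != d[3])
      msg <- c(msg, "'times' length must equal the number of frames")
    if (nt > 1L && any(diff(object@times) <= 0))
      msg <- c(msg, "frame times must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

#' Geometric analysis parameters
#'
#' Thresholds used throughout the analysis.  Defaults follow the standard
#' conventions for amyloid oligomer trajectory analysis: a hydrogen bond is
#' N--O within 3.5 Angstrom with an N-H...O angle of at least 120 degrees, a
#' residue contact is a minimum heavy-atom distance of at most 5.4 Angstrom
#' between residues at least `minSeqSeparation` apart in sequence (interchain
#' pairs are never excluded), gromos clustering uses a 4 Angstrom (0.4 nm)
#' Ca-RMSD cutoff, and free-energy landscapes are evaluated at 310 K.
#'
#' @slot hbondMaxDist maximum donor N to acceptor O distance, Angstrom.
#' @slot hbondMinAngle minimum N-H...O angle, degrees.
#' @slot contactMaxDist maximum heavy-atom distance for a contact, Angstrom.
#' @slot minSeqSeparation minimum |i-j| for an intrachain contact, residues.
#' @slot clusterCutoff gromos clustering cutoff, Angstrom.
#' @slot temperature temperature for free-energy landscapes, Kelvin.
#' @slot sheetMinRun minimum strand length, residues.
#' @slot sheetMinHBonds minimum backbone hydrogen bonds for a sheet pairing.
#'
#' @exportClass AnalysisParameters
setClass("AnalysisParameters",
  representation(
    hbondMaxDist = "numeric",
    hbondMinAngle = "numeric",
    contactMaxDist = "numeric",
    minSeqSeparation = "integer",
    clusterCutoff = "numeric",
    temperature = "numeric",
    sheetMinRun = "integer",
    sheetMinHBonds = "integer"
  ),
  prototype(
    hbondMaxDist = 3.5,
    hbondMinAngle = 120,
    contactMaxDist = 5.4,
    minSeqSeparation = 2L,
    clusterCutoff = 4.0,
    temperature = 310,
    sheetMinRun = 2L,
    sheetMinHBonds = 2L
  )
)

setValidity("AnalysisParameters", function(object) {
  msg <- character()
  if (object@hbondMaxDist <= 0 || object@contactMaxDist <= 0 ||
      object@clusterCutoff <= 0)
    msg <- c(msg, "distance thresholds must be positive")
  if (object@hbondMinAngle <= 0 || object@hbondMinAngle > 180)
    msg <- c(msg, "'hbondMinAngle' must lie in (0, 180]")
  if (object@temperature <= 0)
    msg <- c(msg, "'temperature' must be positive")
  if (object@sheetMinRun < 1L || object@sheetMinHBonds < 1L)
    msg <- c(msg, "sheet thresholds must be at least 1")
  if (length(msg)) msg else TRUE
})

#' Secondary-structure assignment
#'
#' Per-frame, per-residue Kabsch-Sander codes (`H`, `G`, `I`, `E`, `B`, `T`,
#' `S`, `-`) plus the bridge list (residue pairs with parallel/antiparallel
#' orientation) each frame.
#'
#' @slot codes character matrix, residues x frames.
#' @slot residues `data.frame` with columns `chain`, `resno` (row order
#'   matches `codes`).
#' @slot bridges list, one `data.frame` per frame with columns `i`, `j`
#'   (global residue row indices) and `type` (`"parallel"`/`"antiparallel"`).
#'
#' @exportClass SSAssignment
setClass("SSAssignment",
  representation(
    codes = "matrix",
    residues = "data.frame",
    bridges = "list"
  )
)

setValidity("SSAssignment", function(object) {
  msg <- character()
  ok <- c("H", "G", "I", "E", "B", "T", "S", "-")
  if (!all(object@codes %in% ok))
    msg <- c(msg, "codes must be one of H, G, I, E, B, T, S, -")
  if (nrow(object@codes) != nrow(object@residues))
    msg <- c(msg, "one code row per residue required")
  if (length(object@bridges) != ncol(object@codes))
    msg <- c(msg, "one bridge table per frame required")
  if (length(msg)) msg else TRUE
})

#' Beta-sheet pairing graph of one frame
#'
#' Strand segments (maximal runs of `E`) as nodes; edges join strand pairs
#' coupled by at least `sheetMinHBonds` backbone hydrogen bonds, labelled
#' with their orientation.
#'
#' @slot strands `data.frame`: `chain`, `start`, `end` (residue numbers,
#'   inclusive), and direction unit vector columns `dx`, `dy`, `dz`.
#' @slot edges `data.frame`: `s1`, `s2` (strand row indices), `orientation`
#'   (`"parallel"`, `"antiparallel"` or `"indeterminate"`), `nhb`.
#'
#' @exportClass SheetGraph
setClass("SheetGraph",
  representation(strands = "data.frame", edges = "data.frame")
)

#' Oligomer topology class of one frame
#'
#' @slot label one of `"disordered"`, `"single_sheet"`, `"bilayer"`,
#'   `"open_barrel"`, `"closed_barrel"`.
#' @slot strandCounts integer vector: `n` for sheets/barrels, layer sizes
#'   (descending) for bilayers, `integer(0)` for disordered.
#' @slot mixed logical, `TRUE` when both parallel and antiparallel pairings
#'   occur in the frame.
#'
#' @exportClass OligomerClass
setClass("OligomerClass",
  representation(label = "character", strandCounts = "integer",
                 mixed = "logical")
)

setValidity("OligomerClass", function(object) {
  ok <- c("disordered", "single_sheet", "bilayer", "open_barrel",
          "closed_barrel")
  if (!(object@label %in% ok))
    return(sprintf("label must be one of %s", paste(ok, collapse = ", ")))
  if (object@label == "bilayer" && is.unsorted(rev(object@strandCounts)))
    return("bilayer layer sizes must be sorted descending")
  TRUE
})

#' gromos (Daura) clustering result
#'
#' @slot centers integer vector of cluster-center frame indices, in
#'   discovery order (non-increasing cluster sizes).
#' @slot members list of integer vectors partitioning all frames.
#' @slot populations numeric vector of cluster population fractions.
#' @slot cutoff numeric, the RMSD cutoff used (Angstrom).
#'
#' @exportClass ClusterResult
setClass("ClusterResult",
  representation(centers = "integer", members = "list",
                 populations = "numeric", cutoff = "numeric")
)

setValidity("ClusterResult", function(object) {
  msg <- character()
  n <- length(object@centers)
  if (length(object@members) != n || length(object@populations) != n)
    msg <- c(msg, "centers, members and populations must have equal length")
  if (n) {
    sizes <- lengths(object@members)
    if (any(diff(sizes) > 0))
      msg <- c(msg, "cluster sizes must be non-increasing")
    if (abs(sum(object@populations) - 1) > 1e-9)
      msg <- c(msg, "populations must sum to 1")
    all_members <- sort(unlist(object@members))
    if (!identical(all_members, seq_along(all_members)))
      msg <- c(msg, "members must partition the frame indices")
  }
  if (length(msg)) msg else TRUE
})

#' Two-dimensional free-energy landscape
#'
#' Normalized 2D probability histogram `H(x, y)` over two reaction
#' coordinates and the derived potential of mean force
#' `-RT ln H`, shifted so its minimum is 0 (kJ/mol); empty bins are `Inf`.
#'
#' @slot xedges,yedges bin edges.
#' @slot H normalized probability matrix (sums to 1 over occupied bins).
#' @slot pmf potential-of-mean-force matrix, kJ/mol.
#' @slot temperature Kelvin.
#'
#' @exportClass Landscape
setClass("Landscape",
  representation(xedges = "numeric", yedges = "numeric", H = "matrix",
                 pmf = "matrix", temperature = "numeric")
)

setValidity("Landscape", function(object) {
  msg <- character()
  if (nrow(object@H) != length(object@xedges) - 1L ||
      ncol(object@H) != length(object@yedges) - 1L)
    msg <- c(msg, "histogram dimensions must match bin edges")
  if (abs(sum(object@H) - 1) > 1e-9)
    msg <- c(msg, "H must sum to 1")
  occ <- object@H > 0
  if (any(occ) && abs(min(object@pmf[occ]) - 0) > 1e-9)
    msg <- c(msg, "PMF minimum over occupied bins must be 0")
  if (length(msg)) msg else TRUE
})
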