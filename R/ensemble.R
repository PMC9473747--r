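# gas constant, kJ/(mol K)
.R_GAS <- 8.314462e-3

#' Normalized 1D probability density
#'
#' Histogram density of a numeric series; the density integrates to 1
#' (`sum(density * binwidth) = 1`).
#'
#' @param series numeric values (nonempty).
#' @param bins number of bins, or a vector of bin edges.
#' @return `data.frame` with `mid`, `density`, `count`.
#' @export
pdf1d <- function(series, bins = 30L) {
  if (!length(series)) stop("empty series")
  edges <- if (length(bins) > 1L) bins else {
    rng <- range(series)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    seq(rng[1], rng[2], length.out = bins + 1L)
  }
  h <- graphics::hist(series, breaks = edges, plot = FALSE)
  data.frame(mid = h$mids, density = h$density, count = h$counts)
}

#' Two-dimensional free-energy landscape (potential of mean force)
#'
#' Builds the normalized 2D histogram `H(x, y)` of two reaction coordinates
#' and the potential of mean force `-RT ln H`, shifted so that the deepest
#' bin is 0 kJ/mol; empty bins are `Inf`.  The conventional coordinates for
#' amyloid oligomer ensembles are the beta-sheet contact count (x) and the
#' radius of gyration (y).
#'
#' @param x,y equal-length numeric series.
#' @param xbins,ybins bin count or edge vector per axis.  Integer-valued x
#'   series (e.g. contact counts) default to unit-width integer bins.
#' @param temperature Kelvin (default 310).
#' @return a [Landscape-class]; PMF in kJ/mol
#'   (`R = 8.314462e-3 kJ/(mol K)`).
#' @examples
#' l <- pmf2d(c(1, 1, 1, 1, 2), c(0.9, 0.9, 0.9, 0.9, 1.0))
#' pmfMatrix(l)
#' @export
pmf2d <- function(x, y, xbins = NULL, ybins = NULL, temperature = 310) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (!length(x)) stop("empty series")
  xedges <- .axis_edges(x, xbins)
  yedges <- .axis_edges(y, ybins)
  xi <- findInterval(x, xedges, rightmost.closed = TRUE)
  yi <- findInterval(y, yedges, rightmost.closed = TRUE)
  ok <- xi >= 1 & xi <= length(xedges) - 1 & yi >= 1 & yi <= length(yedges) - 1
  H <- matrix(0, length(xedges) - 1L, length(yedges) - 1L)
  for (k in which(ok)) H[xi[k], yi[k]] <- H[xi[k], yi[k]] + 1
  H <- H / sum(H)
  pmf <- -.R_GAS * temperature * log(H)
  occ <- H > 0
  pmf[occ] <- pmf[occ] - min(pmf[occ])
  pmf[!occ] <- Inf
  new("Landscape", xedges = xedges, yedges = yedges, H = H, pmf = pmf,
      temperature = temperature)
}

.axis_edges <- function(v, bins) {
  if (!is.null(bins) && length(bins) > 1L) return(as.numeric(bins))
  if (is.null(bins) && all(v == round(v))) {
    # integer reaction coordinate: unit bins centered on the integers
    return(seq(min(v) - 0.5, max(v) + 0.5, by = 1))
  }
  nb <- if (is.null(bins)) 30L else bins
  rng <- range(v)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  seq(rng[1], rng[2], length.out = nb + 1L)
}

#' Ensemble contact probability maps
#'
#' Per residue-pair contact probabilities over the frames of a window,
#' split into interchain (averaged over all ordered chain pairs) and
#' intrachain (averaged over chains) maps on the peptide sequence positions.
#'
#' @param traj a [PeptideTrajectory-class].
#' @param window frame indices (default: all frames).
#' @param params an [AnalysisParameters-class].
#' @return list of two symmetric matrices (`interchain`, `intrachain`),
#'   sequence-length square, values in `[0, 1]`.
#' @export
contactProbabilityMap <- function(traj, window = NULL,
                                  params = analysisParameters()) {
  stopifnot(is(traj, "PeptideTrajectory"))
  if (is.null(window)) window <- seq_len(nFrames(traj))
  if (!length(window)) stop("empty window")
  sys <- traj@system
  rt <- .residue_table(sys)
  nres <- nchar(sys@sequence)
  pos <- rt$resno - sys@offset + 1L     # 1..nres within each chain
  chains <- sys@chains
  nc <- length(chains)

  inter <- intra <- matrix(0, nres, nres)
  n_inter <- nc * (nc - 1L)
  for (k in window) {
    cm <- residueContacts(getFrame(traj, k), sys, params)
    for (a in seq_len(nrow(rt))) {
      js <- which(cm[a, ])
      for (b in js) {
        i <- pos[a]; j <- pos[b]
        if (rt$chain[a] == rt$chain[b]) intra[i, j] <- intra[i, j] + 1
        else inter[i, j] <- inter[i, j] + 1
      }
    }
  }
  intra <- intra / (length(window) * nc)
  if (n_inter > 0) inter <- inter / (length(window) * n_inter) else inter[] <- 0
  # symmetrize the interchain map over (i, j) -> (j, i)
  inter <- (inter + t(inter)) / 2
  labels <- as.character(sys@offset + seq_len(nres) - 1L)
  dimnames(inter) <- dimnames(intra) <- list(labels, labels)
  list(interchain = inter, intrachain = intra)
}

#' Interaction time series
#'
#' Per-frame counts of intrachain and interchain backbone hydrogen bonds and
#' heavy-atom residue contacts.
#'
#' @param traj a [PeptideTrajectory-class].
#' @param params an [AnalysisParameters-class].
#' @return `data.frame` with `frame`, `time` (ns or `NA`),
#'   `hbIntra`, `hbInter`, `hbTotal`, `contactIntra`, `contactInter`,
#'   `contactTotal`.
#' @export
interactionTimeseries <- function(traj, params = analysisParameters()) {
  stopifnot(is(traj, "PeptideTrajectory"))
  sys <- traj@system
  rt <- .residue_table(sys)
  same_chain <- outer(rt$chain, rt$chain, "==")
  nf <- nFrames(traj)
  out <- data.frame(frame = seq_len(nf),
                    time = if (length(traj@times)) traj@times else NA_real_,
                    hbIntra = 0L, hbInter = 0L, hbTotal = 0L,
                    contactIntra = 0L, contactInter = 0L, contactTotal = 0L)
  for (k in seq_len(nf)) {
    xyz <- getFrame(traj, k)
    hb <- suppressWarnings(detectHBonds(xyz, sys, params))
    out$hbInter[k] <- sum(hb$interchain)
    out$hbIntra[k] <- sum(!hb$interchain)
    cm <- residueContacts(xyz, sys, params)
    ut <- upper.tri(cm)
    out$contactIntra[k] <- sum(cm[ut & same_chain])
    out$contactInter[k] <- sum(cm[ut & !same_chain])
  }
  out$hbTotal <- out$hbIntra + out$hbInter
  out$contactTotal <- out$contactIntra + out$contactInter
  out
}

#' Distribution overlap between two trajectory windows
#'
#' Convergence check: histogram an observable over two disjoint windows on
#' shared bins and return the overlap coefficient
#' `sum(min(pA, pB))`, which is 1 for identical distributions and 0 for
#' disjoint supports.
#'
#' @param traj a [PeptideTrajectory-class].
#' @param windowA,windowB disjoint nonempty frame-index vectors.
#' @param observable function(frame coords, system) -> numeric, or one of
#'   `"hbonds"` (total backbone hydrogen bonds) and `"rg"`.
#' @param bins number of shared bins.
#' @param params an [AnalysisParameters-class].
#' @return overlap coefficient in `[0, 1]`.
#' @export
convergenceOverlap <- function(traj, windowA, windowB,
                               observable = "hbonds", bins = 20L,
                               params = analysisParameters()) {
  stopifnot(is(traj, "PeptideTrajectory"))
  if (!length(windowA) || !length(windowB)) stop("empty window")
  if (length(intersect(windowA, windowB))) stop("windows must be disjoint")
  sys <- traj@system
  fn <- if (is.function(observable)) observable
  else switch(observable,
    hbonds = function(xyz, sys)
      nrow(suppressWarnings(detectHBonds(xyz, sys, params))),
    rg = function(xyz, sys) radiusOfGyration(xyz, sys),
    stop("unknown observable: ", observable))
  va <- vapply(windowA, function(k) fn(getFrame(traj, k), sys), numeric(1))
  vb <- vapply(windowB, function(k) fn(getFrame(traj, k), sys), numeric(1))
  histogramOverlap(va, vb, bins)
}

#' Overlap coefficient of two samples
#'
#' @param a,b numeric samples.
#' @param bins shared bin count.
#' @return `sum(min(pA, pB))` over shared bins.
#' @export
histogramOverlap <- function(a, b, bins = 20L) {
  rng <- range(c(a, b))
  if (diff(rng) == 0) return(1)
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  pa <- graphics::hist(a, breaks = edges, plot = FALSE)$counts / length(a)
  pb <- graphics::hist(b, breaks = edges, plot = FALSE)$counts / length(b)
  sum(pmin(pa, pb))
}

#' Ions needed for a salt concentration in a cubic box
#'
#' Nearest integer to `concentration * volume * N_Avogadro` with the box
#' volume converted to litres; one count per ion species.  At the
#' physiological 0.15 mol/L NaCl this reproduces 10, 18 and 32 ion pairs for
#' cubic boxes of edge 4.757, 5.873 and 7.060 nm.
#'
#' @param concentration mol/L (>= 0).
#' @param boxEdge cubic box edge, nm (> 0).
#' @return integer count per ion species.
#' @examples
#' ionCount(0.15, 4.757)  # 10
#' @export
ionCount <- function(concentration, boxEdge) {
  if (concentration < 0) stop("'concentration' must be >= 0")
  if (boxEdge <= 0) stop("'boxEdge' must be > 0")
  avogadro <- 6.02214076e23
  volume_l <- (boxEdge * 1e-8)^3       # nm -> dm, cubed -> litres
  as.integer(round(concentration * volume_l * avogadro))
}

#' Simulation plan bookkeeping
#'
#' Accumulated simulation time of a plan table (one row per system).
#'
#' @param plan `data.frame` with columns `timePerRun` (microseconds) and
#'   `runs`; extra columns (box edge, peptide count) are carried along.
#' @return total time in microseconds.
#' @examples
#' planTotals(ttrSimulationPlan())  # 31.5
#' @export
planTotals <- function(plan) {
  if (!nrow(plan)) return(0)
  if (any(plan$timePerRun <= 0) || any(plan$runs <= 0))
    stop("plan entries must be positive")
  sum(plan$timePerRun * plan$runs)
}

#' Published simulation plan for TTR(105-115) oligomerization
#'
#' The two-, four- and six-peptide systems: cubic box edges 4.757, 5.873 and
#' 7.060 nm, seven independent 1.5 microsecond runs each, 0.15 mol/L NaCl.
#'
#' @return `data.frame` with columns `system`, `boxEdge` (nm), `peptides`,
#'   `timePerRun` (us), `runs`, and attribute `saltConcentration` (mol/L).
#' @export
ttrSimulationPlan <- function() {
  plan <- data.frame(
    system = c("two-peptides", "four-peptides", "six-peptides"),
    boxEdge = c(4.757, 5.873, 7.060),
    peptides = c(2L, 4L, 6L),
    timePerRun = c(1.5, 1.5, 1.5),
    runs = c(7L, 7L, 7L),
    stringsAsFactors = FALSE
  )
  attr(plan, "saltConcentration") <- 0.15
  plan
}
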