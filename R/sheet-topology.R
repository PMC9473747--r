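#' Find beta-strand segments in one frame
#'
#' Maximal runs of DSSP code `E` of at least `sheetMinRun` residues
#' ("two or more coherent residues"), with the strand direction taken as the
#' unit vector from the first to the last CA of the run.
#'
#' @param ss an [SSAssignment-class].
#' @param frame frame index into `ss` (and the coordinates).
#' @param coords `n_atoms x 3` coordinate matrix of that frame.
#' @param system the [PeptideSystem-class].
#' @param params an [AnalysisParameters-class].
#' @return `data.frame`: `chain`, `start`, `end` (residue numbers,
#'   inclusive), direction components `dx`, `dy`, `dz`.
#' @export
findStrands <- function(ss, frame, coords, system,
                        params = analysisParameters()) {
  stopifnot(is(ss, "SSAssignment"))
  .stop_if_not_system(system)
  xyz <- .as_frame_matrix(coords)
  codes <- ss@codes[, frame]
  rt <- .residue_table(system)
  idxCA <- .atom_index_by_residue(system, "CA")

  out <- list()
  for (ch in system@chains) {
    rows <- which(rt$chain == ch)
    isE <- codes[rows] == "E"
    r <- rle(isE)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= params@sheetMinRun)) {
      gfirst <- rows[starts[k]]
      glast <- rows[ends[k]]
      d <- .unit(xyz[idxCA[glast], ] - xyz[idxCA[gfirst], ])
      out[[length(out) + 1L]] <- data.frame(
        chain = ch, start = rt$resno[gfirst], end = rt$resno[glast],
        dx = d[1], dy = d[2], dz = d[3], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chain = character(0), start = integer(0),
                      end = integer(0), dx = numeric(0), dy = numeric(0),
                      dz = numeric(0), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

# residues (chain, resno) of one strand row
.strand_residues <- function(strands, k) {
  data.frame(chain = strands$chain[k],
             resno = seq(strands$start[k], strands$end[k]))
}

#' Build the beta-sheet pairing graph
#'
#' Two strands are paired ("form a beta-sheet") when at least
#' `sheetMinHBonds` backbone hydrogen bonds (default 2) connect residues of
#' the two segments.  Orientation is parallel when the strand direction dot
#' product exceeds +0.5, antiparallel below -0.5, and indeterminate in the
#' dead zone.
#'
#' @param strands strand table from [findStrands()].
#' @param hbonds backbone hydrogen bonds from [detectHBonds()].
#' @param params an [AnalysisParameters-class].
#' @return a [SheetGraph-class].
#' @export
buildSheetGraph <- function(strands, hbonds, params = analysisParameters()) {
  ns <- nrow(strands)
  edges <- list()
  if (ns >= 2L && nrow(hbonds)) {
    for (a in seq_len(ns - 1L)) {
      ra <- .strand_residues(strands, a)
      keya <- paste(ra$chain, ra$resno)
      for (b in (a + 1L):ns) {
        rb <- .strand_residues(strands, b)
        keyb <- paste(rb$chain, rb$resno)
        dkey <- paste(hbonds$donorChain, hbonds$donorResno)
        akey <- paste(hbonds$acceptorChain, hbonds$acceptorResno)
        nhb <- sum((dkey %in% keya & akey %in% keyb) |
                   (dkey %in% keyb & akey %in% keya))
        if (nhb >= params@sheetMinHBonds) {
          dotp <- sum(unlist(strands[a, c("dx", "dy", "dz")]) *
                      unlist(strands[b, c("dx", "dy", "dz")]))
          orient <- if (dotp > 0.5) "parallel"
                    else if (dotp < -0.5) "antiparallel"
                    else "indeterminate"
          edges[[length(edges) + 1L]] <-
            data.frame(s1 = a, s2 = b, orientation = orient, nhb = nhb,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  edf <- if (length(edges)) do.call(rbind, edges)
  else data.frame(s1 = integer(0), s2 = integer(0),
                  orientation = character(0), nhb = integer(0),
                  stringsAsFactors = FALSE)
  new("SheetGraph", strands = strands, edges = edf)
}

#' Count beta-sheet contacts
#'
#' The reaction coordinate of the free-energy landscape: the number of
#' residue pairs that form the beta-sheet.  In the default `"hbonded"` mode
#' a pair counts when both residues are strand residues of an edge-connected
#' strand pair and are linked by at least one backbone hydrogen bond; the
#' `"paired"` mode counts every residue pair of edge-connected strands
#' regardless of direct hydrogen bonding.
#'
#' @param graph a [SheetGraph-class].
#' @param hbonds backbone hydrogen bonds of the same frame.
#' @param mode `"hbonded"` (default) or `"paired"`.
#' @return integer count.
#' @export
betaSheetContacts <- function(graph, hbonds, mode = c("hbonded", "paired")) {
  mode <- match.arg(mode)
  strands <- graph@strands
  edges <- graph@edges
  if (!nrow(edges)) return(0L)
  total <- 0L
  for (e in seq_len(nrow(edges))) {
    ra <- .strand_residues(strands, edges$s1[e])
    rb <- .strand_residues(strands, edges$s2[e])
    if (mode == "paired") {
      total <- total + nrow(ra) * nrow(rb)
    } else {
      keya <- paste(ra$chain, ra$resno)
      keyb <- paste(rb$chain, rb$resno)
      dkey <- paste(hbonds$donorChain, hbonds$donorResno)
      akey <- paste(hbonds$acceptorChain, hbonds$acceptorResno)
      sel <- (dkey %in% keya & akey %in% keyb) |
             (dkey %in% keyb & akey %in% keya)
      if (any(sel)) {
        pair <- ifelse(paste(hbonds$donorChain, hbonds$donorResno)[sel] %in% keya,
                       paste(dkey[sel], akey[sel]),
                       paste(akey[sel], dkey[sel]))
        total <- total + length(unique(pair))
      }
    }
  }
  as.integer(total)
}

# minimum CA-CA distance between residues of two strands
.strand_min_ca_dist <- function(strands, a, b, xyz, system) {
  idxCA <- .atom_index_by_residue(system, "CA")
  rt <- .residue_table(system)
  rowsA <- rt$chain == strands$chain[a] & rt$resno >= strands$start[a] &
    rt$resno <= strands$end[a]
  rowsB <- rt$chain == strands$chain[b] & rt$resno >= strands$start[b] &
    rt$resno <= strands$end[b]
  ca_a <- xyz[idxCA[which(rowsA)], , drop = FALSE]
  ca_b <- xyz[idxCA[which(rowsB)], , drop = FALSE]
  sqrt(min(.crossdist2(ca_a, ca_b)))
}

#' Classify the oligomer topology of one frame
#'
#' Connected components of the sheet graph are sheets.  Precedence:
#' (1) a component with a simple cycle through at least three strands is a
#' closed barrel (n = cycle length); (2) an acyclic component of at least
#' three strands that curls toward closure is an open barrel -- the curl
#' criterion is a minimum CA-CA distance of at most `curlMaxDist` between
#' the two terminal strands, or an accumulated dihedral between successive
#' strand-pair planes of at least `curlMinAngle`; (3) two sheets of at least
#' two strands each stacked face to face (at least `stackMinContacts`
#' inter-sheet residue contacts but no sheet edge) form a bilayer `[m, n]`
#' (sizes descending); (4) one flat sheet is a single sheet; (5) otherwise
#' the frame is disordered.  The mixed flag is set when both parallel and
#' antiparallel pairings occur.
#'
#' @param graph a [SheetGraph-class].
#' @param coords `n_atoms x 3` coordinates of the frame.
#' @param system the [PeptideSystem-class].
#' @param params an [AnalysisParameters-class].
#' @param contacts optional precomputed [residueContacts()] matrix.
#' @param curlMaxDist,curlMinAngle,stackMinContacts,stackMinSeparation curl
#'   and stacking thresholds (8 Angstrom, 90 degrees, 3 contacts,
#'   3.5 Angstrom).  The separation threshold is the offset of the second
#'   sheet along the first sheet's plane normal; it distinguishes genuinely
#'   stacked layers from coplanar fragments of one sheet.
#' @return an [OligomerClass-class].
#' @export
classifyOligomer <- function(graph, coords, system,
                             params = analysisParameters(),
                             contacts = NULL,
                             curlMaxDist = 8.0, curlMinAngle = 90,
                             stackMinContacts = 3L,
                             stackMinSeparation = 3.5) {
  .stop_if_not_system(system)
  xyz <- .as_frame_matrix(coords)
  strands <- graph@strands
  edges <- graph@edges
  mixed <- all(c("parallel", "antiparallel") %in% edges$orientation)

  if (!nrow(strands) || !nrow(edges))
    return(new("OligomerClass", label = "disordered",
               strandCounts = integer(0), mixed = isTRUE(mixed)))

  g <- igraph::graph_from_data_frame(
    edges[, c("s1", "s2")], directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(strands))))
  comp <- igraph::components(g)
  comp_sizes <- comp$csize
  memb <- comp$membership

  # (1) closed barrel: a cycle through >= 3 strands
  for (cid in order(comp_sizes, decreasing = TRUE)) {
    nodes <- which(memb == cid)
    if (length(nodes) < 3L) next
    sub <- igraph::induced_subgraph(g, nodes)
    if (igraph::ecount(sub) >= igraph::vcount(sub)) {
      girth <- suppressWarnings(igraph::girth(sub)$girth)
      n <- if (is.finite(girth) && girth >= 3) as.integer(girth)
           else length(nodes)
      return(new("OligomerClass", label = "closed_barrel",
                 strandCounts = n, mixed = mixed))
    }
  }

  # (2) open barrel: acyclic component of >= 3 strands that curls
  for (cid in order(comp_sizes, decreasing = TRUE)) {
    nodes <- which(memb == cid)
    if (length(nodes) < 3L) next
    sub <- igraph::induced_subgraph(g, nodes)
    dia <- igraph::get_diameter(sub)
    path <- as.integer(igraph::V(sub)$name[dia])
    if (length(path) < 3L) next
    ends_dist <- .strand_min_ca_dist(strands, path[1],
                                     path[length(path)], xyz, system)
    curl <- .accumulated_curl(strands, path, xyz, system)
    if (ends_dist <= curlMaxDist || curl >= curlMinAngle)
      return(new("OligomerClass", label = "open_barrel",
                 strandCounts = length(nodes), mixed = mixed))
  }

  # (3) bilayer: two stacked sheets without inter-sheet pairing
  sheet_comps <- which(comp_sizes >= 2L)
  if (length(sheet_comps) >= 2L) {
    ord <- sheet_comps[order(comp_sizes[sheet_comps], decreasing = TRUE)]
    c1 <- which(memb == ord[1])
    c2 <- which(memb == ord[2])
    if (is.null(contacts))
      contacts <- residueContacts(xyz, system, params)
    rt <- .residue_table(system)
    rows1 <- .strand_residue_rows(strands, c1, rt)
    rows2 <- .strand_residue_rows(strands, c2, rt)
    ncontact <- sum(contacts[rows1, rows2, drop = FALSE])
    sep <- .sheet_plane_separation(strands, c1, c2, xyz, system)
    nang <- .sheet_normal_angle(strands, c1, c2, xyz, system)
    if (ncontact >= stackMinContacts && sep >= stackMinSeparation &&
        nang <= 45)
      return(new("OligomerClass", label = "bilayer",
                 strandCounts = as.integer(sort(comp_sizes[ord[1:2]],
                                                decreasing = TRUE)),
                 mixed = mixed))
  }

  # (4) single sheet
  if (any(comp_sizes >= 2L)) {
    n <- max(comp_sizes)
    return(new("OligomerClass", label = "single_sheet",
               strandCounts = as.integer(n), mixed = mixed))
  }

  new("OligomerClass", label = "disordered", strandCounts = integer(0),
      mixed = mixed)
}

# angle (degrees, sign-free) between the plane normals of two sheet
# components; stacked bilayer faces are near-parallel even when the strand
# directions are orthogonal, whereas arcs of one curled sheet are not
.sheet_normal_angle <- function(strands, c1, c2, xyz, system) {
  idxCA <- .atom_index_by_residue(system, "CA")
  rt <- .residue_table(system)
  nrm <- function(cc) {
    ca <- xyz[idxCA[.strand_residue_rows(strands, cc, rt)], , drop = FALSE]
    svd(sweep(ca, 2, colMeans(ca)))$v[, 3]
  }
  a <- abs(sum(nrm(c1) * nrm(c2)))
  .rad2deg(acos(max(-1, min(1, a))))
}

# offset of sheet component 2 from the plane of component 1, along the
# normal of component 1 (smallest principal axis of its strand CA cloud)
.sheet_plane_separation <- function(strands, c1, c2, xyz, system) {
  idxCA <- .atom_index_by_residue(system, "CA")
  rt <- .residue_table(system)
  ca1 <- xyz[idxCA[.strand_residue_rows(strands, c1, rt)], , drop = FALSE]
  ca2 <- xyz[idxCA[.strand_residue_rows(strands, c2, rt)], , drop = FALSE]
  ctr <- colMeans(ca1)
  dev <- sweep(ca1, 2, ctr)
  normal <- svd(dev)$v[, 3]
  abs(mean(sweep(ca2, 2, ctr) %*% normal))
}

.strand_residue_rows <- function(strands, strand_ids, rt) {
  rows <- integer(0)
  for (k in strand_ids) {
    rows <- c(rows, which(rt$chain == strands$chain[k] &
                          rt$resno >= strands$start[k] &
                          rt$resno <= strands$end[k]))
  }
  rows
}

# accumulated angle between successive strand-pair plane normals along a
# path of strands; measures how far the sheet curls toward a barrel
.accumulated_curl <- function(strands, path, xyz, system) {
  if (length(path) < 3L) return(0)
  idxCA <- .atom_index_by_residue(system, "CA")
  rt <- .residue_table(system)
  centroid <- function(k) {
    rows <- which(rt$chain == strands$chain[k] &
                  rt$resno >= strands$start[k] & rt$resno <= strands$end[k])
    colMeans(xyz[idxCA[rows], , drop = FALSE])
  }
  dirs <- lapply(path, function(k) unlist(strands[k, c("dx", "dy", "dz")]))
  cents <- lapply(path, centroid)
  normals <- list()
  for (e in seq_len(length(path) - 1L)) {
    axis <- dirs[[e]]
    off <- cents[[e + 1L]] - cents[[e]]
    normals[[e]] <- .unit(.cross(axis, off))
  }
  total <- 0
  for (e in seq_len(length(normals) - 1L)) {
    a <- .rad2deg(acos(max(-1, min(1, abs(sum(normals[[e]] *
                                              normals[[e + 1L]]))))))
    total <- total + a
  }
  total
}

#' Per-frame topology classification of a trajectory
#'
#' Runs [assignSS()], [detectHBonds()], [findStrands()],
#' [buildSheetGraph()], [betaSheetContacts()] and [classifyOligomer()] over
#' every frame.
#'
#' @param traj a [PeptideTrajectory-class].
#' @param params an [AnalysisParameters-class].
#' @param ss optional precomputed [SSAssignment-class].
#' @return `data.frame`: `frame`, `label`, `strands` (e.g. `"5"` or
#'   `"3+2"`), `mixed`, `betaContacts`.
#' @export
classifyFrames <- function(traj, params = analysisParameters(), ss = NULL) {
  stopifnot(is(traj, "PeptideTrajectory"))
  if (is.null(ss)) ss <- assignSS(traj)
  sys <- traj@system
  out <- vector("list", nFrames(traj))
  for (k in seq_len(nFrames(traj))) {
    xyz <- getFrame(traj, k)
    hb <- suppressWarnings(detectHBonds(xyz, sys, params))
    strands <- findStrands(ss, k, xyz, sys, params)
    graph <- buildSheetGraph(strands, hb, params)
    cls <- classifyOligomer(graph, xyz, sys, params)
    out[[k]] <- data.frame(
      frame = k, label = oligomerLabel(cls),
      strands = paste(strandCounts(cls), collapse = "+"),
      mixed = mixedOrientation(cls),
      betaContacts = betaSheetContacts(graph, hb),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}
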