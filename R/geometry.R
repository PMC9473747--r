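#' Detect hydrogen bonds in one frame
#'
#' Geometric criterion: a hydrogen bond exists when the donor N to acceptor
#' O distance is within `hbondMaxDist` (3.5 Angstrom) and the N-H...O angle
#' is at least `hbondMinAngle` (120 degrees), both inclusive.  Donors are
#' amide N-H groups (proline and residues whose amide H can neither be found
#' in the file nor reconstructed are skipped); acceptors are carbonyl oxygens
#' (`"backbone"` scope, including the C-terminal OXT) or all oxygens
#' (`"all-NO"` scope).  When the amide H is absent from the file it is
#' reconstructed 1.01 Angstrom from N in the C(prev)-N-CA plane, opposite
#' the bisector.
#'
#' @param frame an `n_atoms x 3` coordinate matrix (Angstrom) or a one-frame
#'   [PeptideTrajectory-class].
#' @param system the [PeptideSystem-class] the coordinates belong to.
#' @param params an [AnalysisParameters-class].
#' @param scope `"backbone"` (default) or `"all-NO"`.
#' @return `data.frame` with one row per hydrogen bond: `donorChain`,
#'   `donorResno`, `acceptorChain`, `acceptorResno`, `distance` (Angstrom),
#'   `angle` (degrees), `interchain`.  Deduplicated to one row per
#'   donor-acceptor residue pair (shortest N-O distance kept).
#' @examples
#' tr <- assembleState("sheet", nChains = 2, seed = 7)
#' hb <- detectHBonds(getFrame(tr, 1), trajectorySystem(tr))
#' @export
detectHBonds <- function(frame, system, params = analysisParameters(),
                         scope = c("backbone", "all-NO")) {
  scope <- match.arg(scope)
  .stop_if_not_system(system)
  xyz <- .as_frame_matrix(frame)
  at <- system@atoms
  rt <- .residue_table(system)
  nres <- nrow(rt)

  idxN <- .atom_index_by_residue(system, "N")
  idxH <- .atom_index_by_residue(system, "H")
  idxCA <- .atom_index_by_residue(system, "CA")
  idxC <- .atom_index_by_residue(system, "C")

  # donor set: amide N-H per residue
  don_res <- integer(0)
  donN <- donH <- NULL
  skipped <- character(0)
  for (r in seq_len(nres)) {
    if (rt$aa[r] == "P") next
    iN <- idxN[r]
    if (is.na(iN)) next
    if (!is.na(idxH[r])) {
      hpos <- xyz[idxH[r], ]
    } else {
      prev <- r - 1L
      same_chain <- prev >= 1L && rt$chain[prev] == rt$chain[r]
      if (!same_chain || is.na(idxC[prev]) || is.na(idxCA[r])) {
        if (same_chain)
          skipped <- c(skipped, paste0(rt$chain[r], ":", rt$resno[r]))
        next
      }
      npos <- xyz[iN, ]
      hpos <- npos + 1.01 *
        .unit(.unit(npos - xyz[idxC[prev], ]) + .unit(npos - xyz[idxCA[r], ]))
    }
    don_res <- c(don_res, r)
    donN <- rbind(donN, xyz[iN, ])
    donH <- rbind(donH, hpos)
  }
  if (length(skipped))
    warning("residues skipped as donors (no amide H): ",
            paste(skipped, collapse = ", "))

  # acceptor set
  if (scope == "backbone") {
    acc_sel <- which(at$name %in% c("O", "OXT"))
  } else {
    acc_sel <- which(at$element == "O")
  }
  if (!length(don_res) || !length(acc_sel))
    return(.empty_hbond_df())
  acc_res <- .atom_residue_index(system)[acc_sel]
  accO <- xyz[acc_sel, , drop = FALSE]

  d2 <- .crossdist2(donN, accO)
  cand <- which(d2 <= params@hbondMaxDist^2, arr.ind = TRUE)
  if (!nrow(cand)) return(.empty_hbond_df())

  out <- list()
  for (k in seq_len(nrow(cand))) {
    di <- cand[k, 1]
    ai <- cand[k, 2]
    rd <- don_res[di]
    ra <- acc_res[ai]
    if (rd == ra) next
    ang <- .angle3(donN[di, ], donH[di, ], accO[ai, ])
    if (ang < params@hbondMinAngle) next
    out[[length(out) + 1L]] <- data.frame(
      donorChain = rt$chain[rd], donorResno = rt$resno[rd],
      acceptorChain = rt$chain[ra], acceptorResno = rt$resno[ra],
      distance = sqrt(d2[di, ai]), angle = ang,
      interchain = rt$chain[rd] != rt$chain[ra],
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) return(.empty_hbond_df())
  df <- do.call(rbind, out)
  # deduplicate to residue pairs, keeping the shortest N-O distance
  key <- paste(df$donorChain, df$donorResno, df$acceptorChain,
               df$acceptorResno)
  df <- df[order(key, df$distance), ]
  df <- df[!duplicated(paste(df$donorChain, df$donorResno, df$acceptorChain,
                             df$acceptorResno)), ]
  rownames(df) <- NULL
  df
}

.empty_hbond_df <- function() {
  data.frame(donorChain = character(0), donorResno = integer(0),
             acceptorChain = character(0), acceptorResno = integer(0),
             distance = numeric(0), angle = numeric(0),
             interchain = logical(0), stringsAsFactors = FALSE)
}

#' Residue-residue contact map of one frame
#'
#' A residue pair is in contact when the minimum distance between their
#' heavy atoms is at most `contactMaxDist` (5.4 Angstrom).  Intrachain pairs
#' closer than `minSeqSeparation` (2) in sequence are excluded
#' ("discontinuous residues"); interchain pairs are never excluded.
#'
#' @inheritParams detectHBonds
#' @return symmetric logical matrix (residues x residues) with dimnames
#'   `"chain:resno"`; the diagonal and excluded intrachain pairs are `FALSE`.
#' @examples
#' tr <- assembleState("sheet", nChains = 2, seed = 7)
#' cm <- residueContacts(getFrame(tr, 1), trajectorySystem(tr))
#' @export
residueContacts <- function(frame, system, params = analysisParameters()) {
  .stop_if_not_system(system)
  xyz <- .as_frame_matrix(frame)
  rt <- .residue_table(system)
  nres <- nrow(rt)
  heavy <- which(system@atoms$element != "H")
  hres <- .atom_residue_index(system)[heavy]
  hxyz <- xyz[heavy, , drop = FALSE]

  d2 <- .crossdist2(hxyz, hxyz)
  # two-step min-reduction atom blocks -> residue pairs
  tmp <- matrix(Inf, nres, ncol(d2))
  for (r in seq_len(nres)) {
    rows <- which(hres == r)
    if (length(rows))
      tmp[r, ] <- do.call(pmin, c(asplit(d2[rows, , drop = FALSE], 1)))
  }
  mind2 <- matrix(Inf, nres, nres)
  for (r in seq_len(nres)) {
    cols <- which(hres == r)
    if (length(cols))
      mind2[, r] <- do.call(pmin, c(asplit(tmp[, cols, drop = FALSE], 2)))
  }

  contact <- mind2 <= params@contactMaxDist^2
  same_chain <- outer(rt$chain, rt$chain, "==")
  seq_sep <- abs(outer(rt$resno, rt$resno, "-"))
  contact[same_chain & seq_sep < params@minSeqSeparation] <- FALSE
  diag(contact) <- FALSE
  dimnames(contact) <- rep(list(paste0(rt$chain, ":", rt$resno)), 2)
  contact
}

#' Radius of gyration
#'
#' `Rg = sqrt( sum_i m_i |r_i - rbar|^2 / sum_i m_i )` with `rbar` the
#' (mass-weighted) centroid.  The default selection is all peptide heavy
#' atoms, mass-weighted.
#'
#' @inheritParams detectHBonds
#' @param selection integer atom indices (default: all heavy atoms).
#' @param massWeighted logical; unit masses when `FALSE`.
#' @return Rg in Angstrom (>= 0).
#' @examples
#' tr <- assembleState("helix", nChains = 1, seed = 1)
#' radiusOfGyration(getFrame(tr, 1), trajectorySystem(tr))
#' @export
radiusOfGyration <- function(frame, system,
                             selection = selectAtoms(system, "heavy"),
                             massWeighted = TRUE) {
  .stop_if_not_system(system)
  if (!length(selection)) stop("empty selection")
  xyz <- .as_frame_matrix(frame)[selection, , drop = FALSE]
  m <- if (massWeighted)
    .atomic_mass(system@atoms$element[selection])
  else rep(1, length(selection))
  ctr <- colSums(xyz * m) / sum(m)
  dev <- sweep(xyz, 2, ctr)
  sqrt(sum(m * rowSums(dev^2)) / sum(m))
}

.atomic_mass <- function(element) {
  tab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)
  out <- tab[element]
  if (any(is.na(out)))
    stop("unknown element(s): ",
         paste(unique(element[is.na(out)]), collapse = ", "))
  unname(out)
}

# Bondi van der Waals radii, Angstrom
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Point-sampling estimate of the solvent-accessible surface area over the
#' heavy atoms, with Bondi van der Waals radii (C 1.70, N 1.55, O 1.52,
#' S 1.80 Angstrom), a 1.4 Angstrom probe and a deterministic golden-spiral
#' sphere sampling.  Hydrogens are ignored.  The hydrophobic total sums C
#' and S atoms, the hydrophilic total N and O atoms.
#'
#' @inheritParams detectHBonds
#' @param probeRadius probe sphere radius, Angstrom.
#' @param nSpherePoints sampling points per atom sphere.
#' @return list with `atomArea` (per-atom areas, square Angstrom, `NA` for
#'   hydrogens), `hydrophobic`, `hydrophilic` and `total`.
#' @examples
#' tr <- assembleState("helix", nChains = 1, seed = 1)
#' computeSASA(getFrame(tr, 1), trajectorySystem(tr))$total
#' @export
computeSASA <- function(frame, system, probeRadius = 1.4,
                        nSpherePoints = 960L) {
  .stop_if_not_system(system)
  xyz <- .as_frame_matrix(frame)
  el <- system@atoms$element
  heavy <- which(el != "H")
  unknown <- setdiff(el[heavy], names(.VDW_RADII))
  if (length(unknown))
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "))
  radii <- .VDW_RADII[el[heavy]] + probeRadius
  hxyz <- xyz[heavy, , drop = FALSE]
  pts <- .sphere_points(nSpherePoints)

  n <- length(heavy)
  area <- numeric(n)
  d2 <- .crossdist2(hxyz, hxyz)
  for (i in seq_len(n)) {
    ri <- radii[i]
    nb <- which(d2[i, ] < (ri + radii)^2 & seq_len(n) != i)
    p <- sweep(pts * ri, 2, hxyz[i, ], "+")
    acc <- rep(TRUE, nrow(p))
    for (j in nb) {
      if (!any(acc)) break
      dj <- sweep(p[acc, , drop = FALSE], 2, hxyz[j, ])
      acc[acc] <- rowSums(dj^2) > radii[j]^2
    }
    area[i] <- 4 * pi * ri^2 * sum(acc) / nrow(pts)
  }
  atomArea <- rep(NA_real_, nrow(xyz))
  atomArea[heavy] <- area
  list(
    atomArea = atomArea,
    hydrophobic = sum(area[el[heavy] %in% c("C", "S")]),
    hydrophilic = sum(area[el[heavy] %in% c("N", "O")]),
    total = sum(area)
  )
}

# deterministic golden-spiral points on the unit sphere
.sphere_points <- function(n) {
  k <- seq_len(n)
  z <- (2 * k - 1) / n - 1
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  th <- golden * (k - 1)
  cbind(r * cos(th), r * sin(th), z)
}
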