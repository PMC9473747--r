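# Assembly of labelled synthetic oligomer conformations.
#
# All states are geometric constructions (no physics): strands are ideal
# beta chains, sheets are built at 4.8 Angstrom inter-strand spacing with
# the hydrogen-bond registry found by a deterministic axial-shift/pleat
# scan (the chosen placement maximizes the number of detected backbone
# hydrogen bonds between a strand pair, so every generated sheet passes the
# package's own detectors at zero noise), closed barrels place strand axes
# on a cylinder of radius d / (2 sin(pi/n)) with zero shear, open barrels
# use n strands on an (n+1)-slot cylinder (one closure pairing removed),
# bilayers stack two sheets face to face, and coils are self-avoiding
# random dihedral draws with chains kept at least 4 Angstrom apart,
# mirroring the minimum intermolecular separation of oligomerization
# simulations.

.assembly_cache <- new.env(parent = emptyenv())

.SHEET_SPACING <- 4.8      # inter-strand distance, Angstrom
.BILAYER_STACK <- 7.0      # sheet-to-sheet stacking distance, Angstrom

# align a built chain: CA centroid at origin, first->last CA along +z,
# second CA deviation along +x
.align_to_z <- function(xyz, ca) {
  ctr <- colMeans(xyz[ca, , drop = FALSE])
  xyz <- sweep(xyz, 2, ctr)
  z <- .unit(xyz[ca[length(ca)], ] - xyz[ca[1], ])
  v <- .cross(z, c(0, 0, 1))
  s <- .vnorm(v)
  if (s > 1e-9)
    xyz <- xyz %*% t(.rotmat(v, atan2(s, sum(z * c(0, 0, 1)))))
  else if (sum(z * c(0, 0, 1)) < 0)
    xyz <- xyz %*% t(.rotmat(c(1, 0, 0), pi))
  d <- xyz[ca[2], ]
  d[3] <- 0
  if (.vnorm(d) > 1e-9)
    xyz <- xyz %*% t(.rotmat(c(0, 0, 1), -atan2(d[2], d[1])))
  xyz
}

# one aligned ideal beta strand and its (single-chain) system
.beta_strand <- function(sequence, flavor = c("anti", "par")) {
  flavor <- match.arg(flavor)
  key <- paste("strand", sequence, flavor)
  if (!is.null(.assembly_cache[[key]])) return(.assembly_cache[[key]])
  pp <- if (flavor == "anti") c(-139, 135) else c(-119, 113)
  tr <- buildPeptide(sequence, pp[1], pp[2])
  sys <- tr@system
  xyz <- .align_to_z(getFrame(tr, 1), selectAtoms(sys, "calpha"))
  out <- list(xyz = xyz, sys = sys)
  .assembly_cache[[key]] <- out
  out
}

# n-chain system replicating one single-chain atom table
.replicated_system <- function(sys1, n) {
  at1 <- sys1@atoms
  ats <- do.call(rbind, lapply(seq_len(n), function(k) {
    a <- at1
    a$chain <- LETTERS[k]
    a
  }))
  peptideSystem(sys1@sequence, ats, offset = sys1@offset)
}

# margin-aware pair score: interchain Kabsch-Sander bond count plus total
# bond strength capped at 3.5 kcal/mol per bond.  Maximizing this keeps the
# assembled registry far from the -0.5 kcal/mol assignment threshold (so it
# survives coordinate noise) without rewarding unphysically short contacts;
# placements with interchain heavy-atom clashes (< 2.4 Angstrom) score -1.
.pair_score <- function(xA, xB, sys2) {
  fr <- rbind(xA, xB)
  heavy1 <- which(sys2@atoms$element != "H" &
                  sys2@atoms$chain == sys2@chains[1])
  if (min(.crossdist2(xA[heavy1, , drop = FALSE],
                      xB[heavy1, , drop = FALSE])) < 2.4^2) return(-1)
  em <- .ks_energy_matrix(fr, sys2)
  nres <- nchar(sys2@sequence)
  ia <- seq_len(nres)
  ib <- nres + seq_len(nres)
  inter <- c(em[ia, ib], em[ib, ia])
  e <- inter[!is.na(inter) & inter < .DSSP_EMIN]
  if (!length(e)) return(0)
  2 * length(e) + sum(pmin(-e, 3.5))
}

# flat sheet: strands added one by one at +y .SHEET_SPACING from the
# previous strand; for each addition the flip variant and axial shift are
# scanned against the actual previous strand for best H-bond registry
.build_flat_sheet <- function(sequence, n, orientation = "antiparallel") {
  key <- paste("sheet", sequence, n, orientation)
  if (!is.null(.assembly_cache[[key]])) return(.assembly_cache[[key]])
  pat <- switch(orientation,
    antiparallel = rep("antiparallel", max(0L, n - 1L)),
    parallel = rep("parallel", max(0L, n - 1L)),
    mixed = rep(c("antiparallel", "parallel"), length.out = max(0L, n - 1L)),
    stop("unknown orientation pattern: ", orientation))
  st <- .beta_strand(sequence,
                     if (orientation == "parallel") "par" else "anti")
  sys2 <- .replicated_system(st$sys, 2L)
  coords <- list(st$xyz)
  for (k in seq_len(n - 1L)) {
    prev <- coords[[k]]
    ctr <- colMeans(prev)
    flips <- if (pat[k] == "antiparallel")
      list(.rotmat(c(1, 0, 0), pi), .rotmat(c(0, 1, 0), pi))
    else
      list(diag(3), .rotmat(c(0, 0, 1), pi))
    best <- NULL
    for (F in flips) {
      for (dy in c(.SHEET_SPACING, .SHEET_SPACING - 0.15,
                   .SHEET_SPACING + 0.15)) {
        base <- sweep(sweep(prev, 2, ctr) %*% t(F), 2, -ctr)
        base[, 2] <- base[, 2] + dy
        for (dz in seq(-4.5, 4.5, 0.15)) {
          xB <- base
          xB[, 3] <- xB[, 3] + dz
          sc <- .pair_score(prev, xB, sys2)
          if (is.null(best) || sc > best$sc) best <- list(xB = xB, sc = sc)
        }
      }
    }
    coords[[k + 1L]] <- best$xB
  }
  out <- do.call(rbind, coords)
  .assembly_cache[[key]] <- out
  out
}

# barrel: an isometric cylindrical wrap of a periodic antiparallel flat
# sheet.  Strands alternate up/down; the wrap bends the sheet smoothly so
# hydrogen-bond alignment follows the curvature, as the twisted strands of
# real beta-barrels do.  Closed barrels wrap n strands over the full
# circumference (for even n the closure seam is congruent to the interior
# interfaces; odd closed barrels carry one parallel seam); open barrels use
# n strands on an (n + 1)-slot circumference, leaving one pairing open.
# The wrap radius and the radial position of the bending-neutral surface
# are scanned once per configuration for the strongest Kabsch-Sander
# registry on the weakest interface, then cached.
.build_barrel <- function(sequence, n, closed) {
  if (n < 3L) stop("a barrel needs at least 3 strands")
  m <- if (closed) n else n + 1L
  key <- paste("barrel", sequence, n, m, closed)
  if (!is.null(.assembly_cache[[key]])) return(.assembly_cache[[key]])
  st <- .beta_strand(sequence, "anti")
  sys2 <- .replicated_system(st$sys, 2L)
  flipx <- .rotmat(c(1, 0, 0), pi)

  sysn <- .replicated_system(st$sys, n)
  nat <- nrow(st$xyz)
  heavy1 <- which(st$sys@atoms$element != "H")
  nres <- nchar(sequence)
  chain_rows <- lapply(seq_len(n) - 1L, function(k) k * nat + seq_len(nat))

  # interface score on the wrapped coordinates: tiered Kabsch-Sander bond
  # strength of the weakest strand pair; steric overlap anywhere (heavy
  # atoms closer than 2.4 Angstrom) is penalized by its depth so that the
  # least-strained geometry wins even for very tight barrels
  eval_wrap <- function(w) {
    mind <- Inf
    for (a in seq_len(n - 1L)) {
      for (b in (a + 1L):n) {
        d2 <- .crossdist2(w[chain_rows[[a]][heavy1], , drop = FALSE],
                          w[chain_rows[[b]][heavy1], , drop = FALSE])
        mind <- min(mind, min(d2))
      }
    }
    mind <- sqrt(mind)
    if (mind < 2.4) return(-1000 * (2.4 - mind))
    em <- .ks_energy_matrix(w, sysn)
    n_iface <- if (closed) n else n - 1L
    scs <- vapply(seq_len(n_iface) - 1L, function(k) {
      ia <- k * nres + seq_len(nres)
      ib <- (((k + 1L) %% n)) * nres + seq_len(nres)
      e <- c(em[ia, ib], em[ib, ia])
      e <- e[!is.na(e) & e < .DSSP_EMIN]
      if (!length(e)) return(0)
      3 * sum(e <= -2.5) + sum(e <= -1.5) + 0.2 * length(e)
    }, numeric(1))
    min(scs)
  }

  # periodic flat sheet for a given strand spacing and pair shift
  periodic_sheet <- function(dy, dz) {
    B <- st$xyz %*% t(flipx)
    B[, 2] <- B[, 2] + dy
    B[, 3] <- B[, 3] + dz
    do.call(rbind, lapply(seq_len(n) - 1L, function(k) {
      base <- if (k %% 2L == 0L) st$xyz else B
      base[, 2] <- base[, 2] + (k - k %% 2L) * dy
      base
    }))
  }

  # closure fixes R = m * dy / (2 pi); open barrels may deviate slightly
  rfacs <- if (closed) 1 else seq(0.96, 1.08, 0.04)
  best <- NULL
  for (dy in c(4.8, 4.65, 4.95, 5.1)) {
    # pair shift registry for this spacing
    best_dz <- NULL
    for (dz in seq(-2, 2, 0.1)) {
      B <- st$xyz %*% t(flipx)
      B[, 2] <- B[, 2] + dy
      B[, 3] <- B[, 3] + dz
      s <- .pair_score(st$xyz, B, sys2)
      if (is.null(best_dz) || s > best_dz$s) best_dz <- list(dz = dz, s = s)
    }
    flat <- periodic_sheet(dy, best_dz$dz)
    for (rfac in rfacs) {
      R <- m * dy / (2 * pi) * rfac
      for (x0 in seq(-0.5, 2, 0.25)) {
        th <- flat[, 2] / R
        w <- cbind((R + flat[, 1] - x0) * cos(th),
                   (R + flat[, 1] - x0) * sin(th),
                   flat[, 3])
        s <- eval_wrap(w)
        if (is.null(best) || s > best$s) best <- list(w = w, s = s)
      }
    }
  }
  .assembly_cache[[key]] <- best$w
  best$w
}

# bilayer: two flat antiparallel sheets stacked face to face along the
# sheet normal, the upper sheet shifted half a strand spacing laterally
.build_bilayer <- function(sequence, layers) {
  m <- layers[1]
  n <- layers[2]
  a <- .build_flat_sheet(sequence, m)
  b <- .build_flat_sheet(sequence, n)
  # center each sheet in the strand-stacking (y) direction
  a[, 2] <- a[, 2] - mean(range(a[, 2]))
  b[, 2] <- b[, 2] - mean(range(b[, 2])) + .SHEET_SPACING / 2
  b <- b %*% t(.rotmat(c(0, 0, 1), pi))     # oppose the faces
  b[, 1] <- b[, 1] + .BILAYER_STACK
  rbind(a, b)
}

# random-coil chain: self-avoiding random dihedrals, re-drawn until free of
# clashes and of any helix/strand assignment
.random_coil_chain <- function(sequence, max_tries = 60L) {
  nres <- nchar(sequence)
  for (try in seq_len(max_tries)) {
    phi <- stats::runif(nres, -160, -50)
    psi <- ifelse(stats::runif(nres) < 0.4,
                  stats::runif(nres, -60, -10),
                  stats::runif(nres, 100, 170))
    tr <- buildPeptide(sequence, phi, psi)
    xyz <- getFrame(tr, 1)
    sys <- tr@system
    heavy <- selectAtoms(sys, "heavy")
    d2 <- .crossdist2(xyz[heavy, , drop = FALSE], xyz[heavy, , drop = FALSE])
    res <- .atom_residue_index(sys)[heavy]
    apart <- abs(outer(res, res, "-")) >= 2L
    if (any(d2[apart] < 2.2^2)) next
    codes <- suppressWarnings(assignSS(xyz, sys))@codes[, 1]
    if (any(codes %in% c("E", "B", "H"))) next
    return(xyz)
  }
  xyz   # last attempt as fallback (practically unreachable)
}

# place chain coordinate blocks far apart on a cubic grid, guaranteeing a
# minimum inter-chain atom distance
.place_apart <- function(chains, min_gap = 4.5) {
  n <- length(chains)
  radii <- vapply(chains, function(x)
    max(sqrt(rowSums(sweep(x, 2, colMeans(x))^2))), numeric(1))
  spacing <- 2 * max(radii) + min_gap
  side <- ceiling(n^(1 / 3))
  out <- vector("list", n)
  for (k in seq_len(n)) {
    i <- (k - 1L) %% side
    j <- ((k - 1L) %/% side) %% side
    l <- (k - 1L) %/% (side * side)
    ctr <- colMeans(chains[[k]])
    out[[k]] <- sweep(chains[[k]], 2, ctr - spacing * c(i, j, l))
  }
  do.call(rbind, out)
}

#' Assemble a labelled synthetic oligomer state
#'
#' Builds one conformation of `nChains` copies of the peptide in a requested
#' structural state -- the states observed in oligomerization ensembles of
#' short amyloidogenic peptides: random coil, alpha-helix, single-layer
#' beta-sheets (parallel/antiparallel/mixed), m+n sheet bilayers, and open or
#' closed n-stranded beta-barrels -- and attaches the ground-truth label.
#' Isotropic Gaussian coordinate noise is added; `noise` quotes the
#' root-mean-square displacement per atom (so each coordinate receives
#' Gaussian noise of standard deviation `noise / sqrt(3)`).
#'
#' @param kind one of `"coil"`, `"helix"`, `"sheet"`, `"bilayer"`,
#'   `"open_barrel"`, `"closed_barrel"`.
#' @param nChains number of peptide copies (barrels need >= 3; bilayers
#'   >= 4).
#' @param noise RMS atomic displacement of the isotropic Gaussian
#'   coordinate noise, Angstrom.
#' @param seed integer seed; every random draw (noise, coil dihedrals) flows
#'   through it.
#' @param orientation sheet orientation pattern (`"antiparallel"`,
#'   `"parallel"`, `"mixed"`).
#' @param layers two-layer composition for bilayers (default splits
#'   `nChains` as evenly as possible, larger layer first).
#' @param sequence peptide sequence (default TTR(105-115)).
#' @return a one-frame [PeptideTrajectory-class]; the ground truth is
#'   available via [groundTruthLabel()].
#' @examples
#' tr <- assembleState("closed_barrel", nChains = 6, seed = 1)
#' groundTruthLabel(tr)$label
#' @export
assembleState <- function(kind = c("coil", "helix", "sheet", "bilayer",
                                   "open_barrel", "closed_barrel"),
                          nChains = 2L, noise = 0, seed = NULL,
                          orientation = "antiparallel", layers = NULL,
                          sequence = "YTIAALLSPYS") {
  kind <- match.arg(kind)
  nChains <- as.integer(nChains)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (kind %in% c("open_barrel", "closed_barrel") && nChains < 3L)
    stop("a barrel needs at least 3 strands")
  if (kind == "sheet" && nChains < 2L)
    stop("a sheet needs at least 2 strands")
  if (kind == "bilayer") {
    if (is.null(layers))
      layers <- c(ceiling(nChains / 2), floor(nChains / 2))
    layers <- as.integer(sort(layers, decreasing = TRUE))
    if (sum(layers) != nChains || any(layers < 2L))
      stop("bilayer layers must each have >= 2 strands and sum to nChains")
  }

  st <- .beta_strand(sequence)
  sys <- .replicated_system(st$sys, nChains)

  xyz <- switch(kind,
    coil = .place_apart(lapply(seq_len(nChains), function(k)
      .random_coil_chain(sequence))),
    helix = {
      h <- buildPeptide(sequence, -57, -47)
      hx <- .align_to_z(getFrame(h, 1),
                        selectAtoms(h@system, "calpha"))
      .place_apart(rep(list(hx), nChains))
    },
    sheet = .build_flat_sheet(sequence, nChains, orientation),
    bilayer = .build_bilayer(sequence, layers),
    open_barrel = .build_barrel(sequence, nChains, closed = FALSE),
    closed_barrel = .build_barrel(sequence, nChains, closed = TRUE)
  )
  if (noise > 0)
    xyz <- xyz + stats::rnorm(length(xyz), 0, noise / sqrt(3))

  label <- switch(kind,
    coil = ,
    helix = list(label = "disordered", strandCounts = integer(0)),
    sheet = list(label = "single_sheet", strandCounts = nChains),
    bilayer = list(label = "bilayer", strandCounts = layers),
    open_barrel = list(label = "open_barrel", strandCounts = nChains),
    closed_barrel = list(label = "closed_barrel", strandCounts = nChains)
  )
  out <- peptideTrajectory(sys, xyz)
  attr(out, "groundTruth") <- c(
    list(kind = kind, nChains = nChains, sigma = noise,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         orientation = if (kind == "sheet") orientation else NA_character_),
    label)
  out
}

#' Ground-truth label of a synthetic state
#'
#' @param x an object returned by [assembleState()].
#' @return list with `kind`, `label`, `strandCounts`, `sigma`, `seed`,
#'   `orientation`, `nChains`.
#' @export
groundTruthLabel <- function(x) {
  gt <- attr(x, "groundTruth")
  if (is.null(gt)) stop("no ground-truth label attached")
  gt
}

#' Generate a labelled pseudo-trajectory
#'
#' Concatenates synthetic states into a multi-frame trajectory following a
#' schedule (emulating, e.g., a coil -> sheet -> barrel aggregation
#' progression), optionally writing a multi-model PDB plus a JSON
#' ground-truth sidecar listing the per-frame labels and the seed.
#' Disordered states are redrawn every frame; ordered states are the cached
#' ideal geometry with fresh noise per frame.
#'
#' @param schedule list of stages, each a list with `kind`, `frames`, and
#'   optionally `orientation`, `layers`, `noise`.
#' @param nChains chain count shared by all stages.
#' @param seed integer seed for the whole trajectory.
#' @param noise default per-stage RMS-displacement noise, Angstrom.
#' @param path optional output PDB path.
#' @param sidecarPath optional output JSON path (defaults to
#'   `<path>.json` when `path` is given).
#' @param frameInterval frame spacing, ns.
#' @param sequence peptide sequence.
#' @return list with `trajectory` ([PeptideTrajectory-class]) and
#'   `groundTruth` (`data.frame`: `frame`, `kind`, `label`, `strands`,
#'   `sigma`).
#' @examples
#' out <- makeTrajectory(list(list(kind = "coil", frames = 2),
#'                            list(kind = "sheet", frames = 2)),
#'                       nChains = 2, seed = 42)
#' out$groundTruth
#' @export
makeTrajectory <- function(schedule, nChains, seed, noise = 0.1,
                           path = NULL, sidecarPath = NULL,
                           frameInterval = 0.1,
                           sequence = "YTIAALLSPYS") {
  if (!length(schedule)) stop("empty schedule")
  set.seed(as.integer(seed))
  frames <- list()
  gt <- list()
  for (stg in schedule) {
    stopifnot(!is.null(stg$kind), !is.null(stg$frames))
    sigma <- if (is.null(stg$noise)) noise else stg$noise
    for (f in seq_len(stg$frames)) {
      st <- assembleState(stg$kind, nChains = nChains, noise = sigma,
                          seed = NULL,
                          orientation = if (is.null(stg$orientation))
                            "antiparallel" else stg$orientation,
                          layers = stg$layers, sequence = sequence)
      frames[[length(frames) + 1L]] <- getFrame(st, 1)
      lab <- groundTruthLabel(st)
      gt[[length(gt) + 1L]] <- data.frame(
        frame = length(frames), kind = lab$kind, label = lab$label,
        strands = paste(lab$strandCounts, collapse = "+"),
        sigma = sigma, stringsAsFactors = FALSE)
    }
  }
  sys <- .replicated_system(.beta_strand(sequence)$sys, nChains)
  times <- (seq_along(frames) - 1) * frameInterval
  traj <- peptideTrajectory(sys, frames, times = times)
  gtdf <- do.call(rbind, gt)

  if (!is.null(path)) {
    writeMultimodelPDB(traj, path)
    if (is.null(sidecarPath)) sidecarPath <- paste0(path, ".json")
  }
  if (!is.null(sidecarPath)) {
    jsonlite::write_json(
      list(seed = as.integer(seed), frameInterval = frameInterval,
           nChains = nChains, sequence = sequence, frames = gtdf),
      sidecarPath, auto_unbox = TRUE, digits = NA)
  }
  list(trajectory = traj, groundTruth = gtdf)
}
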