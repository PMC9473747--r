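# Internal geometry helpers. All lengths Angstrom, all angles degrees at the
# API surface (radians internally where noted).

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

# angle a-b-c at vertex b, degrees
.angle3 <- function(a, b, c) {
  u <- .unit(a - b)
  v <- .unit(c - b)
  .rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

# dihedral a-b-c-d, degrees in (-180, 180]
.dihedral <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  m1 <- .cross(n1, .unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  .rad2deg(atan2(y, x))
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Natural-extension-reference-frame atom placement: position D such that
# |C-D| = r, angle(B,C,D) = theta (deg), dihedral(A,B,C,D) = chi (deg).
.place_atom <- function(a, b, c, r, theta, chi) {
  th <- .deg2rad(theta)
  ph <- .deg2rad(chi)
  bc <- .unit(c - b)
  n <- .unit(.cross(b - a, bc))
  m <- .cross(n, bc)
  d2 <- c(-r * cos(th), r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# rotation matrix about unit axis by angle (radians)
.rotmat <- function(axis, angle) {
  u <- .unit(axis)
  ct <- cos(angle)
  st <- sin(angle)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct), ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct), uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

# apply rotation R (3x3) then translation t to an n x 3 coordinate matrix
.transform_coords <- function(xyz, R = diag(3), t = c(0, 0, 0)) {
  sweep(xyz %*% t(R), 2, -t)
}

# squared-distance cross matrix between two n x 3 / m x 3 coordinate sets
.crossdist2 <- function(a, b) {
  an <- rowSums(a * a)
  bn <- rowSums(b * b)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# residue table: one row per (chain, resno) in chain-then-resno order,
# with the one-letter code and a global index used throughout
.residue_table <- function(system) {
  seqv <- strsplit(system@sequence, "")[[1]]
  nres <- length(seqv)
  resno <- system@offset + seq_len(nres) - 1L
  out <- data.frame(
    chain = rep(system@chains, each = nres),
    resno = rep(resno, times = length(system@chains)),
    aa = rep(seqv, times = length(system@chains)),
    stringsAsFactors = FALSE
  )
  out$index <- seq_len(nrow(out))
  out
}

# map each atom row to its global residue index (per .residue_table order)
.atom_residue_index <- function(system) {
  rt <- .residue_table(system)
  key <- paste(system@atoms$chain, system@atoms$resno)
  match(key, paste(rt$chain, rt$resno))
}

# index of one named atom per residue; NA when absent
.atom_index_by_residue <- function(system, atom_name) {
  rt <- .residue_table(system)
  at <- system@atoms
  sel <- which(at$name == atom_name)
  idx <- rep(NA_integer_, nrow(rt))
  pos <- match(paste(at$chain[sel], at$resno[sel]), paste(rt$chain, rt$resno))
  idx[pos] <- sel
  idx
}

.stop_if_not_system <- function(system) {
  if (!is(system, "PeptideSystem"))
    stop("'system' must be a PeptideSystem")
}

.as_frame_matrix <- function(frame) {
  if (is(frame, "PeptideTrajectory")) {
    if (nFrames(frame) != 1L)
      stop("pass a single frame (use getFrame()) or a one-frame trajectory")
    return(getFrame(frame, 1L))
  }
  m <- as.matrix(frame)
  if (ncol(m) != 3L) stop("frame coordinates must be an n x 3 matrix")
  storage.mode(m) <- "double"
  m
}

# element from a PDB atom name (backbone/sidechain heavy atoms + hydrogens)
.element_from_name <- function(name) {
  nm <- toupper(trimws(name))
  first <- substring(nm, 1L, 1L)
  el <- ifelse(grepl("^[0-9]", nm) | first == "H", "H", first)
  el[first %in% c("C", "N", "O", "S")] <- first[first %in% c("C", "N", "O", "S")]
  el
}
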