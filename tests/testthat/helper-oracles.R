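# Independent oracles used to cross-check the package implementations.

# Quaternion (characteristic-polynomial-free) RMSD oracle: the minimum RMSD
# over proper rotations is obtained from the largest eigenvalue of the 4x4
# key matrix built from the covariance of the centered coordinate sets.
qcp_rmsd <- function(a, b) {
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  n <- nrow(a)
  M <- crossprod(a, b)              # 3x3 covariance
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(a^2) + sum(b^2) - 2 * lambda) / n
  sqrt(max(0, msd))
}

# Reference implementation of the gromos (Daura) clustering: recompute the
# neighbor counts from scratch every round with plain scans.
daura_reference <- function(rmsd, cutoff) {
  remaining <- seq_len(nrow(rmsd))
  centers <- integer(0)
  members <- list()
  while (length(remaining)) {
    counts <- vapply(remaining, function(i)
      sum(rmsd[i, remaining] < cutoff), integer(1))
    center <- remaining[which.max(counts)]
    cluster <- remaining[rmsd[center, remaining] < cutoff]
    centers <- c(centers, center)
    members[[length(members) + 1L]] <- sort(cluster)
    remaining <- setdiff(remaining, cluster)
  }
  list(centers = centers, members = members)
}

# Analytic accessible area of sphere 1 of two overlapping spheres
# (radii already include the probe): the accessible cap area is
# 4 pi r1^2 - 2 pi r1 h with h the height of the buried cap.
two_sphere_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * r1^2)
  if (d <= abs(r1 - r2)) return(if (r1 > r2) 4 * pi * r1^2 else 0)
  h <- (r2^2 - (d - r1)^2) / (2 * d)
  4 * pi * r1^2 - 2 * pi * r1 * h
}

# Reference DSSP via mdtraj (the same Kabsch-Sander algorithm,
# independently implemented); one python call for a batch of PDB files.
mdtraj_dssp <- function(pdb_paths) {
  script <- file.path(tempdir(), "dssp_oracle.py")
  if (!file.exists(script)) {
    writeLines(c(
      "import sys, mdtraj as md",
      "for path in sys.argv[1:]:",
      "    t = md.load(path)",
      "    d = md.compute_dssp(t, simplified=False)",
      "    for k in range(d.shape[0]):",
      "        print(path + '\\t' + str(k) + '\\t' + ",
      "              ''.join('-' if c in (' ','') else c for c in d[k]))"
    ), script)
  }
  out <- system2("python", c(script, pdb_paths), stdout = TRUE)
  parts <- strsplit(out, "\t", fixed = TRUE)
  data.frame(path = vapply(parts, `[[`, "", 1),
             frame = as.integer(vapply(parts, `[[`, "", 2)) + 1L,
             codes = vapply(parts, `[[`, "", 3),
             stringsAsFactors = FALSE)
}

# our assignment as one string per frame
ss_string <- function(ss, frame = 1L) {
  paste(ssCodes(ss)[, frame], collapse = "")
}
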