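#' Minimum RMSD under optimal superposition (Kabsch)
#'
#' Root-mean-square deviation between two coordinate sets after optimal
#' rigid superposition (rotation + translation, proper rotation enforced by
#' the Kabsch singular-value-decomposition construction).
#'
#' @param a,b `n x 3` coordinate matrices with matched rows (`n >= 3`,
#'   non-collinear).
#' @return RMSD in Angstrom.
#' @examples
#' set.seed(1)
#' a <- matrix(rnorm(30), 10, 3)
#' kabschRMSD(a, a)  # 0
#' @export
kabschRMSD <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b) || ncol(a) != 3L || ncol(b) != 3L)
    stop("'a' and 'b' must be n x 3 matrices with equal n")
  n <- nrow(a)
  if (n < 3L) stop("at least 3 atoms are required for superposition")
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  if (sum(svd(ac)$d > 1e-8) < 2L || sum(svd(bc)$d > 1e-8) < 2L)
    stop("degenerate (collinear) geometry")
  s <- svd(crossprod(bc, ac))          # covariance of b against a
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  diff <- bc %*% R - ac
  sqrt(sum(diff^2) / n)
}

# all chain-relabeling permutations of atom indices (identical peptides
# are physically interchangeable)
.chain_permutations <- function(system) {
  chains <- system@chains
  perm_list <- .permutations(length(chains))
  at_chain <- system@atoms$chain
  lapply(perm_list, function(p) {
    unlist(lapply(chains[p], function(ch) which(at_chain == ch)))
  })
}

.permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in .permutations(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos)
    }
  }
  out
}

#' Pairwise CA-RMSD matrix of a trajectory
#'
#' Superposition fit and RMSD are both computed on the CA atoms of all
#' residues.  With `permuteChains = TRUE` the RMSD of each frame pair is
#' minimized over relabelings of the (identical) chains; the default keeps
#' the fixed chain order, matching standard gromos clustering on
#' multi-peptide systems.
#'
#' @param traj a [PeptideTrajectory-class].
#' @param selection atom indices used for the fit (default: all CA).
#' @param permuteChains minimize over chain permutations (exhaustive).
#' @return symmetric numeric matrix of RMSD values, Angstrom.
#' @export
rmsdMatrix <- function(traj, selection = NULL, permuteChains = FALSE) {
  stopifnot(is(traj, "PeptideTrajectory"))
  sys <- traj@system
  if (is.null(selection)) selection <- selectAtoms(sys, "calpha")
  nf <- nFrames(traj)
  m <- matrix(0, nf, nf)
  perms <- if (permuteChains) {
    # permuted row order of the selected atoms, per chain relabeling
    lapply(.chain_permutations(sys), function(idx)
      match(idx[idx %in% selection], selection))
  } else NULL
  coords <- lapply(seq_len(nf), function(k)
    getFrame(traj, k)[selection, , drop = FALSE])
  for (i in seq_len(nf - 1L)) {
    for (j in (i + 1L):nf) {
      if (is.null(perms)) {
        r <- kabschRMSD(coords[[i]], coords[[j]])
      } else {
        r <- min(vapply(perms, function(p)
          kabschRMSD(coords[[i]], coords[[j]][p, , drop = FALSE]),
          numeric(1)))
      }
      m[i, j] <- m[j, i] <- r
    }
  }
  m
}

#' gromos (Daura) conformational clustering
#'
#' Greedy clustering of frames on an RMSD matrix: repeatedly take the frame
#' with the most neighbors within the cutoff (ties broken toward the lowest
#' frame index), form a cluster of it and its neighbors, remove them, and
#' iterate until no frames remain.  The neighbor relation is strict
#' (`< cutoff`).  The standard cutoff is 4 Angstrom (0.4 nm).
#'
#' @param rmsd symmetric frame-by-frame RMSD matrix, Angstrom.
#' @param cutoff neighbor cutoff, Angstrom.
#' @return a [ClusterResult-class]; clusters are ordered by discovery
#'   (non-increasing size) and populations sum to 1.
#' @examples
#' m <- matrix(10, 4, 4); diag(m) <- 0
#' m[1, 2] <- m[2, 1] <- 1
#' dauraCluster(m, cutoff = 2)
#' @export
dauraCluster <- function(rmsd, cutoff = 4.0) {
  rmsd <- as.matrix(rmsd)
  if (nrow(rmsd) != ncol(rmsd)) stop("'rmsd' must be square")
  if (max(abs(rmsd - t(rmsd))) > 1e-9) stop("'rmsd' must be symmetric")
  nf <- nrow(rmsd)
  remaining <- rep(TRUE, nf)
  centers <- integer(0)
  members <- list()
  while (any(remaining)) {
    idx <- which(remaining)
    nb <- lapply(idx, function(i) idx[rmsd[i, idx] < cutoff])  # includes i
    sizes <- lengths(nb)
    best <- which.max(sizes)                  # ties -> lowest frame index
    centers <- c(centers, idx[best])
    members[[length(members) + 1L]] <- sort(nb[[best]])
    remaining[nb[[best]]] <- FALSE
  }
  # greedy extraction yields non-increasing sizes by construction
  new("ClusterResult",
      centers = centers,
      members = members,
      populations = lengths(members) / nf,
      cutoff = cutoff)
}
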