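.SS_CATEGORIES <- c("coil", "beta-sheet", "alpha-helix", "bend", "turn")

#' Secondary-structure ensemble statistics
#'
#' Category probabilities over a window of frames: the overall probability
#' of each of the five reporting categories (coil, beta-sheet, alpha-helix,
#' bend, turn) and the per-residue profiles averaged over chains and frames.
#' Probabilities are fractions of (frame, residue) observations, so the five
#' categories sum to 1.
#'
#' @param traj a [PeptideTrajectory-class].
#' @param window frame indices (default: all frames).
#' @param ss optional precomputed [SSAssignment-class].
#' @param table DSSP-code-to-category map; see [defaultSSCategoryTable()].
#' @return list with `overall` (named numeric, sums to 1) and `perResidue`
#'   (sequence positions x categories matrix, each row sums to 1).
#' @examples
#' tr <- assembleState("helix", nChains = 1, seed = 1)
#' ssStatistics(tr)$overall
#' @export
ssStatistics <- function(traj, window = NULL, ss = NULL,
                         table = defaultSSCategoryTable()) {
  stopifnot(is(traj, "PeptideTrajectory"))
  if (is.null(window)) window <- seq_len(nFrames(traj))
  if (!length(window) || any(window < 1L) || any(window > nFrames(traj)))
    stop("empty or out-of-range window")
  if (is.null(ss)) ss <- assignSS(traj)
  cats <- collapseCategories(ss, table)[, window, drop = FALSE]
  sys <- traj@system
  rt <- .residue_table(sys)
  pos <- rt$resno - sys@offset + 1L
  nres <- nchar(sys@sequence)

  per <- matrix(0, nres, length(.SS_CATEGORIES),
                dimnames = list(as.character(sys@offset + seq_len(nres) - 1L),
                                .SS_CATEGORIES))
  for (cat in .SS_CATEGORIES) {
    hits <- cats == cat
    per[, cat] <- vapply(seq_len(nres), function(i)
      mean(hits[pos == i, , drop = FALSE]), numeric(1))
  }
  overall <- colMeans(per)
  list(overall = overall, perResidue = per)
}

#' Per-residue secondary-structure timeline
#'
#' Category of every residue in every frame, as a raster suitable for
#' time-evolution plots (one row per chain and residue, one column per
#' frame).
#'
#' @inheritParams ssStatistics
#' @return character matrix, `(n_chains * sequence length) x n_frames`,
#'   rownames `"chain:resno"`.
#' @export
ssTimeline <- function(traj, ss = NULL, table = defaultSSCategoryTable()) {
  stopifnot(is(traj, "PeptideTrajectory"))
  if (is.null(ss)) ss <- assignSS(traj)
  collapseCategories(ss, table)
}
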