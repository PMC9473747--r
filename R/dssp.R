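# Kabsch-Sander secondary-structure assignment.
#
# Backbone hydrogen bonds are scored with the electrostatic model
# E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) kcal/mol, a bond
# existing when E < -0.5 kcal/mol.  The amide H is placed 1.0 Angstrom from
# N along the C(prev)->O(prev) carbonyl direction, as in the published
# algorithm.  n-turns give H/G/I, bridge ladders give E/B (parallel and
# antiparallel ladder rules, inter-chain bridges permitted), remaining turns
# give T, and bend (kappa > 70 degrees) gives S.

.DSSP_Q <- 0.084 * 332          # kcal/mol * Angstrom
.DSSP_EMIN <- -0.5              # bond threshold, kcal/mol
.DSSP_CA_CUTOFF <- 9.0          # Angstrom, candidate-pair prefilter

# Kabsch-Sander hydrogen-bond energy matrix (acceptor x donor) of one
# frame; entries are NA where no candidate bond exists.  Used by the
# assignment below and by the synthetic builder to maximize bond margins.
.ks_energy_matrix <- function(xyz, system) {
  rt <- .residue_table(system)
  nres <- nrow(rt)
  chain <- rt$chain
  pos <- function(nm) {
    idx <- .atom_index_by_residue(system, nm)
    out <- matrix(NA_real_, nres, 3)
    ok <- !is.na(idx)
    out[ok, ] <- xyz[idx[ok], , drop = FALSE]
    out
  }
  N <- pos("N"); C <- pos("C"); O <- pos("O")
  H <- matrix(NA_real_, nres, 3)
  for (i in seq_len(nres)[-1]) {
    if (chain[i] != chain[i - 1L] || rt$aa[i] == "P") next
    co <- C[i - 1L, ] - O[i - 1L, ]
    H[i, ] <- N[i, ] + co / .vnorm(co)
  }
  em <- matrix(NA_real_, nres, nres)
  okO <- !is.na(O[, 1])
  okH <- !is.na(H[, 1])
  rON2 <- .crossdist2(O, N)
  rON2[!okO, ] <- Inf
  rON2[, !okH] <- Inf
  cand <- which(rON2 < 5.5^2, arr.ind = TRUE)
  if (nrow(cand)) {
    a <- cand[, 1]
    b <- cand[, 2]
    keep <- a != b & !(chain[a] == chain[b] & b == a + 1L)
    a <- a[keep]; b <- b[keep]
    if (length(a)) {
      rON <- sqrt(rON2[cbind(a, b)])
      rCH <- sqrt(rowSums((C[a, , drop = FALSE] - H[b, , drop = FALSE])^2))
      rOH <- sqrt(rowSums((O[a, , drop = FALSE] - H[b, , drop = FALSE])^2))
      rCN <- sqrt(rowSums((C[a, , drop = FALSE] - N[b, , drop = FALSE])^2))
      e <- .DSSP_Q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      e[pmin(rON, rCH, rOH, rCN) < 0.5] <- -9.9
      em[cbind(a, b)] <- e
    }
  }
  em
}

# core assignment for one frame; returns list(codes, bridges)
.dssp_frame <- function(xyz, system, rt, bb) {
  nres <- nrow(rt)
  codes <- rep("-", nres)

  getpos <- function(idx) {
    out <- matrix(NA_real_, nres, 3)
    ok <- !is.na(idx)
    out[ok, ] <- xyz[idx[ok], , drop = FALSE]
    out
  }
  N <- getpos(bb$N); CA <- getpos(bb$CA); C <- getpos(bb$C); O <- getpos(bb$O)

  chain <- rt$chain
  prev_same <- c(FALSE, chain[-1] == chain[-nres])
  complete <- !is.na(bb$N) & !is.na(bb$CA) & !is.na(bb$C) & !is.na(bb$O)

  # chains shorter than 3 residues cannot carry any assignment
  short <- names(which(table(chain) < 3))
  if (length(short)) {
    warning("chain(s) shorter than 3 residues assigned '-': ",
            paste(short, collapse = ", "))
    complete[chain %in% short] <- FALSE
  }

  # Kabsch-Sander amide H: 1 Angstrom from N along the previous carbonyl
  H <- matrix(NA_real_, nres, 3)
  donor <- rep(FALSE, nres)
  for (i in seq_len(nres)) {
    if (!complete[i] || rt$aa[i] == "P" || !prev_same[i]) next
    if (!complete[i - 1L]) next
    co <- C[i - 1L, ] - O[i - 1L, ]
    H[i, ] <- N[i, ] + co / .vnorm(co)
    donor[i] <- TRUE
  }

  # hydrogen-bond matrix: hb[acc, don]
  hb <- matrix(FALSE, nres, nres)
  ok <- which(complete)
  if (length(ok) >= 2L) {
    d2 <- .crossdist2(CA[ok, , drop = FALSE], CA[ok, , drop = FALSE])
    cand <- which(d2 < .DSSP_CA_CUTOFF^2, arr.ind = TRUE)
    cand <- cand[cand[, 1] != cand[, 2], , drop = FALSE]
    if (nrow(cand)) {
      acc <- ok[cand[, 1]]
      don <- ok[cand[, 2]]
      keep <- donor[don] &
        !(chain[acc] == chain[don] & don == acc + 1L)  # own peptide bond
      acc <- acc[keep]; don <- don[keep]
      if (length(acc)) {
        rON <- sqrt(rowSums((O[acc, , drop = FALSE] - N[don, , drop = FALSE])^2))
        rCH <- sqrt(rowSums((C[acc, , drop = FALSE] - H[don, , drop = FALSE])^2))
        rOH <- sqrt(rowSums((O[acc, , drop = FALSE] - H[don, , drop = FALSE])^2))
        rCN <- sqrt(rowSums((C[acc, , drop = FALSE] - N[don, , drop = FALSE])^2))
        e <- .DSSP_Q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
        e[rON < 0.5 | rCH < 0.5 | rOH < 0.5 | rCN < 0.5] <- -9.9
        hb[cbind(acc, don)] <- e < .DSSP_EMIN
      }
    }
  }

  # n-turns: CO(i) ... HN(i+n) within one chain
  turn <- function(s) {
    t <- rep(FALSE, nres)
    if (nres <= s) return(t)
    i <- seq_len(nres - s)
    same <- chain[i] == chain[i + s]
    t[i] <- same & hb[cbind(i, i + s)]
    t
  }
  t3 <- turn(3L); t4 <- turn(4L); t5 <- turn(5L)

  # bridges
  inner <- which(complete &
                 c(FALSE, chain[-1] == chain[-nres]) &
                 c(chain[-nres] == chain[-1], FALSE))
  bridges <- list()
  for (ii in seq_along(inner)) {
    i <- inner[ii]
    for (j in inner[-seq_len(ii)]) {
      if (chain[i] == chain[j] && j < i + 3L) next
      par <- (hb[j, i + 1L] && hb[i - 1L, j]) ||
             (hb[i, j + 1L] && hb[j - 1L, i])
      anti <- (hb[i, j] && hb[j, i]) ||
              (hb[j - 1L, i + 1L] && hb[i - 1L, j + 1L])
      if (par || anti)
        bridges[[length(bridges) + 1L]] <-
          list(i = i, j = j, type = if (par) "parallel" else "antiparallel")
    }
  }

  bridge_df <- if (length(bridges)) {
    data.frame(i = vapply(bridges, `[[`, integer(1), "i"),
               j = vapply(bridges, `[[`, integer(1), "j"),
               type = vapply(bridges, `[[`, character(1), "type"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(i = integer(0), j = integer(0), type = character(0),
               stringsAsFactors = FALSE)
  }

  # ladders: consecutive bridges of one type
  nb <- nrow(bridge_df)
  ladder_id <- seq_len(nb)
  if (nb > 1L) {
    for (a in seq_len(nb - 1L)) {
      for (b in (a + 1L):nb) {
        if (bridge_df$type[a] != bridge_df$type[b]) next
        di <- bridge_df$i[b] - bridge_df$i[a]
        dj <- bridge_df$j[b] - bridge_df$j[a]
        same_strands <- chain[bridge_df$i[a]] == chain[bridge_df$i[b]] &&
          chain[bridge_df$j[a]] == chain[bridge_df$j[b]]
        contiguous <- same_strands &&
          if (bridge_df$type[a] == "parallel") (di == 1L && dj == 1L)
          else (di == 1L && dj == -1L)
        if (contiguous) ladder_id[ladder_id == ladder_id[b]] <- ladder_id[a]
      }
    }
  }

  # beta-bulges: ladders of one type joined by a short irregularity
  # (at most 1 extra residue on one strand and at most 4 on the other)
  merged <- ladder_id
  if (nb > 1L) {
    lads <- unique(merged)
    for (a_id in lads) {
      for (b_id in lads) {
        if (a_id >= b_id) next
        if (!any(merged == a_id) || !any(merged == b_id)) next
        A <- bridge_df[merged == a_id, , drop = FALSE]
        B <- bridge_df[merged == b_id, , drop = FALSE]
        if (A$type[1] != B$type[1]) next
        linked <- FALSE
        for (ka in seq_len(nrow(A))) {
          for (kb in seq_len(nrow(B))) {
            g1 <- abs(B$i[kb] - A$i[ka]) - 1L
            g2 <- abs(B$j[kb] - A$j[ka]) - 1L
            if (chain[A$i[ka]] != chain[B$i[kb]] ||
                chain[A$j[ka]] != chain[B$j[kb]]) next
            if (g1 < 0L || g2 < 0L) next
            if ((g1 <= 1L && g2 <= 4L) || (g1 <= 4L && g2 <= 1L)) {
              linked <- TRUE
              break
            }
          }
          if (linked) break
        }
        if (linked) merged[merged == b_id] <- a_id
      }
    }
  }

  # E for multi-bridge (or bulge-linked) ladders, B for isolated bridges
  if (nb) {
    for (id in unique(merged)) {
      sel <- which(merged == id)
      if (length(sel) == 1L) {
        b <- bridge_df[sel, ]
        if (codes[b$i] == "-") codes[b$i] <- "B"
        if (codes[b$j] == "-") codes[b$j] <- "B"
      } else {
        sub <- bridge_df[sel, , drop = FALSE]
        irange <- range(sub$i)
        jrange <- range(sub$j)
        codes[irange[1]:irange[2]] <- "E"
        codes[jrange[1]:jrange[2]] <- "E"
      }
    }
  }

  # helices: two consecutive n-turns
  set_helix <- function(codes, tflag, span, code, strict) {
    idx <- which(tflag)
    for (i in idx) {
      if (i < 2L || !tflag[i - 1L]) next
      tgt <- i:(i + span - 1L)
      if (max(tgt) > nres) next
      if (strict && !all(codes[tgt] %in% c("-", code))) next
      codes[tgt] <- code
    }
    codes
  }
  codes <- set_helix(codes, t4, 4L, "H", strict = FALSE)
  codes <- set_helix(codes, t3, 3L, "G", strict = TRUE)
  codes <- set_helix(codes, t5, 5L, "I", strict = TRUE)

  # turns
  for (s in c(3L, 4L, 5L)) {
    tflag <- switch(as.character(s), "3" = t3, "4" = t4, "5" = t5)
    for (i in which(tflag)) {
      tgt <- (i + 1L):(i + s - 1L)
      tgt <- tgt[tgt <= nres]
      codes[tgt][codes[tgt] == "-"] <- "T"
    }
  }

  # bend: kappa > 70 degrees
  for (i in seq_len(nres)) {
    if (codes[i] != "-") next
    if (i < 3L || i > nres - 2L) next
    if (chain[i - 2L] != chain[i] || chain[i + 2L] != chain[i]) next
    if (!complete[i - 2L] || !complete[i] || !complete[i + 2L]) next
    u <- CA[i, ] - CA[i - 2L, ]
    v <- CA[i + 2L, ] - CA[i, ]
    kappa <- .rad2deg(acos(max(-1, min(1, sum(.unit(u) * .unit(v))))))
    if (kappa > 70) codes[i] <- "S"
  }

  list(codes = codes, bridges = bridge_df)
}

#' Kabsch-Sander secondary-structure assignment
#'
#' Assigns per-residue DSSP codes (`H`, `G`, `I`, `E`, `B`, `T`, `S`, `-`)
#' to every frame.  Backbone hydrogen bonds use the Kabsch-Sander
#' electrostatic energy with a -0.5 kcal/mol threshold; the amide hydrogen
#' is always placed geometrically from the preceding carbonyl, so heavy-atom
#' input suffices.  Inter-chain bridges are permitted (required for
#' interpeptide sheets); bridges and turns never span a chain terminus.
#'
#' @param x a [PeptideTrajectory-class], or an `n_atoms x 3` coordinate
#'   matrix together with `system`.
#' @param system the [PeptideSystem-class] (ignored when `x` is a
#'   trajectory).
#' @return an [SSAssignment-class].
#' @examples
#' tr <- assembleState("helix", nChains = 1, seed = 1)
#' ssCodes(assignSS(tr))
#' @export
assignSS <- function(x, system = NULL) {
  if (is(x, "PeptideTrajectory")) {
    system <- x@system
    frames <- seq_len(nFrames(x))
    getx <- function(k) getFrame(x, k)
  } else {
    .stop_if_not_system(system)
    frames <- 1L
    getx <- function(k) .as_frame_matrix(x)
  }
  rt <- .residue_table(system)
  bb <- list(N = .atom_index_by_residue(system, "N"),
             CA = .atom_index_by_residue(system, "CA"),
             C = .atom_index_by_residue(system, "C"),
             O = .atom_index_by_residue(system, "O"))
  codes <- matrix("-", nrow(rt), length(frames))
  bridges <- vector("list", length(frames))
  for (k in frames) {
    res <- .dssp_frame(getx(k), system, rt, bb)
    codes[, k] <- res$codes
    bridges[[k]] <- res$bridges
  }
  rownames(codes) <- paste0(rt$chain, ":", rt$resno)
  new("SSAssignment", codes = codes,
      residues = rt[, c("chain", "resno")], bridges = bridges)
}

#' Default secondary-structure category table
#'
#' Collapse of the eight DSSP codes to the five reporting categories:
#' `E` is beta-sheet, `H` is alpha-helix, `T` turn, `S` bend, and `G`, `I`,
#' `B` and `-` are coil.  Isolated beta-bridges count as coil because a
#' sheet requires two or more coherent strand residues; 3-10 and pi helices
#' count as coil so that only `H` reports as alpha-helix.  Users may remap.
#'
#' @return named character vector mapping DSSP code to category.
#' @export
defaultSSCategoryTable <- function() {
  c(H = "alpha-helix", G = "coil", I = "coil", E = "beta-sheet",
    B = "coil", T = "turn", S = "bend", "-" = "coil")
}

#' Collapse DSSP codes to reporting categories
#'
#' @param ss an [SSAssignment-class].
#' @param table named code-to-category map; see [defaultSSCategoryTable()].
#' @return character matrix (residues x frames) of categories.
#' @export
collapseCategories <- function(ss, table = defaultSSCategoryTable()) {
  stopifnot(is(ss, "SSAssignment"))
  codes <- ss@codes
  missing_codes <- setdiff(unique(as.vector(codes)), names(table))
  if (length(missing_codes))
    stop("codes missing from the category table: ",
         paste(missing_codes, collapse = ", "))
  out <- matrix(table[codes], nrow(codes), ncol(codes),
                dimnames = dimnames(codes))
  out
}
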