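# Residue composition tables and ideal-geometry peptide construction.
#
# Atom rosters are for the mid-chain (in-chain) form of each residue at
# physiological protonation (Asp/Glu deprotonated, Lys/Arg protonated,
# His neutral).  Heavy-atom names follow PDB conventions; hydrogens are
# counted and named positionally (H1..Hk) since 3D builds only carry the
# amide H.

.HEAVY_ATOMS <- list(
  G = c("N", "CA", "C", "O"),
  A = c("N", "CA", "C", "O", "CB"),
  S = c("N", "CA", "C", "O", "CB", "OG"),
  C = c("N", "CA", "C", "O", "CB", "SG"),
  T = c("N", "CA", "C", "O", "CB", "OG1", "CG2"),
  V = c("N", "CA", "C", "O", "CB", "CG1", "CG2"),
  P = c("N", "CA", "C", "O", "CB", "CG", "CD"),
  I = c("N", "CA", "C", "O", "CB", "CG1", "CG2", "CD1"),
  L = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2"),
  M = c("N", "CA", "C", "O", "CB", "CG", "SD", "CE"),
  N = c("N", "CA", "C", "O", "CB", "CG", "OD1", "ND2"),
  D = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
  Q = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "NE2"),
  E = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2"),
  K = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"),
  H = c("N", "CA", "C", "O", "CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  F = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  R = c("N", "CA", "C", "O", "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  Y = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ",
        "OH"),
  W = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3",
        "CZ2", "CZ3", "CH2")
)

# hydrogens of the mid-chain form (amide H included except proline)
.HYDROGEN_COUNT <- c(
  G = 3L, A = 5L, S = 5L, C = 5L, T = 7L, V = 9L, P = 7L, I = 11L, L = 11L,
  M = 9L, N = 6L, D = 4L, Q = 8L, E = 6L, K = 13L, H = 7L, F = 9L, R = 13L,
  Y = 9L, W = 10L
)

#' Atom roster of one amino acid
#'
#' Mid-chain atom roster (heavy atoms with PDB names plus positionally named
#' hydrogens) at physiological protonation.  Glycine has 7 atoms, alanine 10.
#'
#' @param aa one-letter amino-acid code.
#' @return `data.frame` with columns `name` and `element`.
#' @export
residueComposition <- function(aa) {
  if (!aa %in% names(.HEAVY_ATOMS)) stop("unknown residue letter: ", aa)
  heavy <- .HEAVY_ATOMS[[aa]]
  nh <- .HYDROGEN_COUNT[[aa]]
  data.frame(
    name = c(heavy, paste0("H", seq_len(nh))),
    element = c(.element_from_name(heavy), rep("H", nh)),
    stringsAsFactors = FALSE
  )
}

#' Count the atoms of a peptide
#'
#' All-atom count of a linear peptide at standard stoichiometry.  With
#' `termini = "charged"` the termini are the zwitterionic forms (ammonium
#' NH3+, two extra hydrogens over the mid-chain amide; carboxylate COO-,
#' one extra oxygen).  With `termini = "neutral"` they are NH2 / COOH.
#' The TTR(105-115) fragment YTIAALLSPYS with charged termini has 172 atoms.
#'
#' @param sequence one-letter amino-acid string.
#' @param termini `"charged"` (default) or `"neutral"`.
#' @return integer atom count.
#' @examples
#' countAtoms("YTIAALLSPYS")   # 172
#' countAtoms("G")             # 10, the glycine zwitterion C2H5NO2
#' @export
countAtoms <- function(sequence, termini = c("charged", "neutral")) {
  termini <- match.arg(termini)
  aas <- strsplit(sequence, "")[[1]]
  if (!length(aas)) stop("empty sequence")
  unknown <- setdiff(aas, names(.HEAVY_ATOMS))
  if (length(unknown))
    stop("unknown residue letter(s): ", paste(unique(unknown), collapse = ", "))
  midchain <- sum(vapply(aas, function(a)
    length(.HEAVY_ATOMS[[a]]) + .HYDROGEN_COUNT[[a]], integer(1)))
  nterm <- switch(termini, charged = 2L, neutral = 1L)   # extra N-term H
  cterm <- switch(termini, charged = 1L, neutral = 2L)   # extra O (+H)
  as.integer(midchain + nterm + cterm)
}

# ideal backbone geometry (Angstrom / degrees)
.BOND_N_CA <- 1.458
.BOND_CA_C <- 1.525
.BOND_C_N <- 1.329
.BOND_C_O <- 1.231
.BOND_N_H <- 1.01
.BOND_CA_CB <- 1.521
.ANGLE_N_CA_C <- 111.2
.ANGLE_CA_C_N <- 116.2
.ANGLE_C_N_CA <- 121.7
.ANGLE_CA_C_O <- 120.8
.ANGLE_N_CA_CB <- 110.5

#' Build a single peptide chain with ideal geometry
#'
#' Constructs one chain with standard bond lengths and angles
#' (N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom, trans peptide bonds)
#' from per-residue backbone dihedrals.  Atoms per residue: N, amide H
#' (except proline and the first residue), CA, CB (except glycine), C, O,
#' plus OXT on the last residue.  Consecutive CA-CA distances are ~3.80
#' Angstrom.
#'
#' @param sequence one-letter amino-acid string.
#' @param phi,psi backbone dihedrals in degrees, one per residue (recycled
#'   if length 1).  `phi[1]` is unused.
#' @param chain chain identifier.
#' @param offset residue number of the first residue.
#' @return a one-frame [PeptideTrajectory-class].
#' @examples
#' helix <- buildPeptide("YTIAALLSPYS", phi = -57, psi = -47)
#' @export
buildPeptide <- function(sequence, phi, psi, chain = "A", offset = 105L) {
  aas <- strsplit(sequence, "")[[1]]
  n <- length(aas)
  if (n < 1L) stop("empty sequence")
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)

  Npos <- CApos <- Cpos <- matrix(NA_real_, n, 3)
  # first residue in a canonical frame
  Npos[1, ] <- c(0, 0, 0)
  CApos[1, ] <- c(.BOND_N_CA, 0, 0)
  ang <- .deg2rad(180 - .ANGLE_N_CA_C)
  Cpos[1, ] <- CApos[1, ] + .BOND_CA_C * c(cos(ang), sin(ang), 0)
  for (i in seq_len(n)[-1]) {
    Npos[i, ] <- .place_atom(Npos[i - 1, ], CApos[i - 1, ], Cpos[i - 1, ],
                             .BOND_C_N, .ANGLE_CA_C_N, psi[i - 1])
    CApos[i, ] <- .place_atom(CApos[i - 1, ], Cpos[i - 1, ], Npos[i, ],
                              .BOND_N_CA, .ANGLE_C_N_CA, 180)
    Cpos[i, ] <- .place_atom(Cpos[i - 1, ], Npos[i, ], CApos[i, ],
                             .BOND_CA_C, .ANGLE_N_CA_C, phi[i])
  }

  rows <- list()
  xyz <- list()
  add <- function(name, pos) {
    rows[[length(rows) + 1L]] <<- name
    xyz[[length(xyz) + 1L]] <<- pos
  }
  for (i in seq_len(n)) {
    add("N", Npos[i, ])
    if (i > 1L && aas[i] != "P") {
      h <- Npos[i, ] + .BOND_N_H *
        .unit(.unit(Npos[i, ] - Cpos[i - 1, ]) + .unit(Npos[i, ] - CApos[i, ]))
      add("H", h)
    }
    add("CA", CApos[i, ])
    if (aas[i] != "G") {
      cb <- .place_atom(Npos[i, ], Cpos[i, ], CApos[i, ],
                        .BOND_CA_CB, .ANGLE_N_CA_CB, 122.6)
      add("CB", cb)
    }
    add("C", Cpos[i, ])
    o <- .place_atom(Npos[i, ], CApos[i, ], Cpos[i, ],
                     .BOND_C_O, .ANGLE_CA_C_O, psi[i] + 180)
    add("O", o)
    if (i == n) {
      oxt <- .place_atom(Npos[i, ], CApos[i, ], Cpos[i, ],
                         .BOND_C_O, 117, psi[i])
      add("OXT", oxt)
    }
  }
  names_vec <- unlist(rows)
  coords <- do.call(rbind, xyz)
  # residue assignment mirrors the add order above
  resnos <- integer(0)
  for (i in seq_len(n)) {
    cnt <- 2L +                                   # N, CA
      (i > 1L && aas[i] != "P") +                 # H
      (aas[i] != "G") +                           # CB
      2L +                                        # C, O
      (i == n)                                    # OXT
    resnos <- c(resnos, rep(offset + i - 1L, cnt))
  }
  atoms <- data.frame(
    name = names_vec,
    element = .element_from_name(names_vec),
    chain = chain,
    resno = resnos,
    stringsAsFactors = FALSE
  )
  sys <- peptideSystem(sequence, atoms, offset = offset)
  peptideTrajectory(sys, coords)
}
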