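test_that("strand segments are maximal E runs of at least two residues", {
  tr <- assembleState("sheet", nChains = 2, seed = 71)
  sys <- trajectorySystem(tr)
  xyz <- getFrame(tr, 1)
  ss <- assignSS(tr)
  strands <- findStrands(ss, 1, xyz, sys)
  expect_equal(nrow(strands), 2L)
  expect_true(all(strands$end - strands$start + 1 >= 2))
  # directions are unit vectors, antiparallel across the pair
  d1 <- unlist(strands[1, c("dx", "dy", "dz")])
  d2 <- unlist(strands[2, c("dx", "dy", "dz")])
  expect_equal(sum(d1^2), 1, tolerance = 1e-9)
  expect_lt(sum(d1 * d2), -0.5)

  # hand-built assignment: an isolated E never seeds a segment,
  # an all-coil frame yields none
  codes <- matrix(c("-", "E", "-", "-", "E", "E", "E", "-", "-", "-", "-"),
                  ncol = 1)
  rt <- OligoTraj:::.residue_table(trajectorySystem(buildPeptide(TTR_SEQ,
                                                                 -139, 135)))
  ssh <- new("SSAssignment", codes = codes,
             residues = rt[, c("chain", "resno")],
             bridges = list(data.frame(i = integer(0), j = integer(0),
                                       type = character(0))))
  one <- buildPeptide(TTR_SEQ, -139, 135)
  st1 <- findStrands(ssh, 1, getFrame(one, 1), trajectorySystem(one))
  expect_equal(nrow(st1), 1L)
  expect_equal(st1$start, 109L)  # 105-based numbering of the E run
  expect_equal(st1$end, 111L)

  codes[] <- "-"
  ssh@codes <- codes
  expect_equal(nrow(findStrands(ssh, 1, getFrame(one, 1),
                                trajectorySystem(one))), 0L)
})

test_that("sheet pairing needs at least two backbone hydrogen bonds", {
  tr <- assembleState("sheet", nChains = 2, seed = 72)
  sys <- trajectorySystem(tr)
  xyz <- getFrame(tr, 1)
  ss <- assignSS(tr)
  strands <- findStrands(ss, 1, xyz, sys)
  hb <- detectHBonds(xyz, sys)
  g <- buildSheetGraph(strands, hb)
  expect_equal(nrow(sheetEdges(g)), 1L)
  expect_equal(sheetEdges(g)$orientation, "antiparallel")
  expect_gte(sheetEdges(g)$nhb, 2)

  # exactly one hydrogen bond between the strands: no edge
  inter <- hb[hb$interchain, ]
  one_hb <- rbind(inter[1, ], hb[!hb$interchain, ])
  g1 <- buildSheetGraph(strands, one_hb)
  expect_equal(nrow(sheetEdges(g1)), 0L)
  # no hydrogen bonds at all: empty edge set
  g0 <- buildSheetGraph(strands, hb[0, ])
  expect_equal(nrow(sheetEdges(g0)), 0L)
})

test_that("beta-sheet contacts count H-bond-linked strand residue pairs", {
  tr <- assembleState("sheet", nChains = 2, seed = 73)
  sys <- trajectorySystem(tr)
  xyz <- getFrame(tr, 1)
  ss <- assignSS(tr)
  strands <- findStrands(ss, 1, xyz, sys)
  hb <- detectHBonds(xyz, sys)
  g <- buildSheetGraph(strands, hb)
  bc <- betaSheetContacts(g, hb)
  expect_gt(bc, 0)
  # never exceeds the interchain hydrogen-bond count
  expect_lte(bc, sum(hb$interchain))
  # a coil frame counts zero
  coil <- assembleState("coil", nChains = 2, seed = 74)
  cxyz <- getFrame(coil, 1)
  css <- assignSS(coil)
  chb <- detectHBonds(cxyz, sys)
  cg <- buildSheetGraph(findStrands(css, 1, cxyz, sys), chb)
  expect_equal(betaSheetContacts(cg, chb), 0L)
  # the paired mode counts all residue pairs of paired strands
  expect_gte(betaSheetContacts(g, hb, mode = "paired"), bc)
})

test_that("bound on beta contacts holds across random noisy frames", {
  set.seed(75)
  for (rep in 1:5) {
    tr <- assembleState("sheet", nChains = 4, noise = 0.25)
    sys <- trajectorySystem(tr)
    xyz <- getFrame(tr, 1)
    ss <- suppressWarnings(assignSS(tr))
    hb <- suppressWarnings(detectHBonds(xyz, sys))
    g <- buildSheetGraph(findStrands(ss, 1, xyz, sys), hb)
    expect_lte(betaSheetContacts(g, hb), sum(hb$interchain))
  }
})

test_that("classifier recovers each constructed topology at zero noise", {
  cases <- list(
    list(kind = "coil", n = 4, label = "disordered", counts = integer(0)),
    list(kind = "helix", n = 4, label = "disordered", counts = integer(0)),
    list(kind = "sheet", n = 2, label = "single_sheet", counts = 2L),
    list(kind = "sheet", n = 4, label = "single_sheet", counts = 4L),
    list(kind = "bilayer", n = 5, layers = c(3, 2), label = "bilayer",
         counts = c(3L, 2L)),
    list(kind = "bilayer", n = 6, layers = c(3, 3), label = "bilayer",
         counts = c(3L, 3L)),
    list(kind = "open_barrel", n = 5, label = "open_barrel", counts = 5L),
    list(kind = "closed_barrel", n = 4, label = "closed_barrel",
         counts = 4L),
    list(kind = "closed_barrel", n = 6, label = "closed_barrel",
         counts = 6L)
  )
  for (cs in cases) {
    tr <- assembleState(cs$kind, nChains = cs$n, seed = 76,
                        layers = cs$layers)
    df <- suppressWarnings(classifyFrames(tr))
    expect_equal(df$label, cs$label, label = cs$kind)
    expect_equal(df$strands, paste(cs$counts, collapse = "+"),
                 label = cs$kind)
  }
})

test_that("classification is invariant under chain relabeling and motion", {
  tr <- assembleState("bilayer", nChains = 5, seed = 77, layers = c(3, 2))
  sys <- trajectorySystem(tr)
  xyz <- getFrame(tr, 1)
  base <- suppressWarnings(classifyFrames(tr))

  # rigid motion
  set.seed(78)
  moved <- apply_rigid(xyz, random_rotation(), c(-12, 4, 30))
  mv <- suppressWarnings(classifyFrames(peptideTrajectory(sys, moved)))
  expect_equal(mv$label, base$label)
  expect_equal(mv$strands, base$strands)

  # chain relabeling: permute the chain blocks
  at <- atomData(sys)
  perm <- c(3, 1, 5, 2, 4)
  idx <- unlist(lapply(LETTERS[perm], function(ch) which(at$chain == ch)))
  at2 <- at[idx, ]
  at2$chain <- rep(LETTERS[1:5], times = tabulate(match(at$chain, LETTERS))[perm])
  sys2 <- peptideSystem(TTR_SEQ, at2, offset = 105L)
  rl <- suppressWarnings(classifyFrames(peptideTrajectory(sys2, xyz[idx, ])))
  expect_equal(rl$label, base$label)
  expect_equal(rl$strands, base$strands)
})

test_that("the mixed-orientation flag reflects the pairing pattern", {
  tr <- assembleState("sheet", nChains = 4, seed = 79,
                      orientation = "mixed")
  df <- suppressWarnings(classifyFrames(tr))
  expect_true(df$mixed)
  tra <- assembleState("sheet", nChains = 4, seed = 79)
  expect_false(suppressWarnings(classifyFrames(tra))$mixed)
})
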