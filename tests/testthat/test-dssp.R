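test_that("ideal helix assigns H to core residues", {
  tr <- buildPeptide(TTR_SEQ, -57, -47)
  ss <- assignSS(tr)
  codes <- unname(ssCodes(ss)[, 1])
  expect_true(all(codes[3:9] == "H"))
  expect_equal(codes[1], "-")
})

test_that("an isolated extended chain has no strand assignment", {
  tr <- buildPeptide(TTR_SEQ, -139, 135)
  codes <- ssCodes(assignSS(tr))[, 1]
  expect_false(any(codes %in% c("E", "B")))
})

test_that("antiparallel dimer yields paired E with antiparallel bridges", {
  tr <- assembleState("sheet", nChains = 2, seed = 21)
  ss <- assignSS(tr)
  codes <- ssCodes(ss)[, 1]
  expect_gte(sum(codes[1:11] == "E"), 2)
  expect_gte(sum(codes[12:22] == "E"), 2)
  br <- ssBridges(ss)[[1]]
  expect_gt(nrow(br), 0)
  expect_true(all(br$type == "antiparallel"))
  # parallel sheets flag parallel bridges
  trp <- assembleState("sheet", nChains = 2, seed = 21,
                       orientation = "parallel")
  brp <- ssBridges(assignSS(trp))[[1]]
  inter <- brp[(brp$i <= 11) != (brp$j <= 11), ]
  expect_gt(nrow(inter), 0)
  expect_true(all(inter$type == "parallel"))
})

test_that("assignment agrees with the reference DSSP implementation", {
  paths <- character(0)
  ours <- character(0)
  add <- function(traj) {
    f <- tempfile(fileext = ".pdb")
    writeMultimodelPDB(traj, f)
    paths <<- c(paths, f)
    ss <- suppressWarnings(assignSS(traj))
    ours <<- c(ours, vapply(seq_len(nFrames(traj)),
                            function(k) ss_string(ss, k), character(1)))
  }
  add(buildPeptide(TTR_SEQ, -57, -47))
  add(buildPeptide(TTR_SEQ, -139, 135))
  add(assembleState("sheet", nChains = 2, seed = 31))
  add(assembleState("sheet", nChains = 4, seed = 32))
  add(assembleState("sheet", nChains = 4, seed = 33, orientation = "parallel"))
  add(assembleState("bilayer", nChains = 5, seed = 34, layers = c(3, 2)))
  add(assembleState("open_barrel", nChains = 5, seed = 35))
  add(assembleState("closed_barrel", nChains = 6, seed = 36))
  add(assembleState("coil", nChains = 4, seed = 37))
  add(assembleState("helix", nChains = 3, seed = 38))

  ref <- mdtraj_dssp(paths)
  ref <- ref[order(match(ref$path, paths), ref$frame), ]
  expect_equal(length(ours), nrow(ref))
  ours_chr <- unlist(strsplit(ours, ""))
  ref_chr <- unlist(strsplit(ref$codes, ""))
  expect_equal(length(ours_chr), length(ref_chr))
  agreement <- mean(ours_chr == ref_chr)
  expect_gte(agreement, 0.95)
})

test_that("assignment is invariant under rigid-body motion", {
  tr <- assembleState("bilayer", nChains = 6, seed = 41, layers = c(3, 3))
  sys <- trajectorySystem(tr)
  xyz <- getFrame(tr, 1)
  set.seed(5)
  moved <- apply_rigid(xyz, random_rotation(), c(25, -3, 7))
  expect_identical(ssCodes(assignSS(moved, sys)),
                   ssCodes(assignSS(xyz, sys)))
})

test_that("category collapse follows the default table and flags gaps", {
  tr <- buildPeptide(TTR_SEQ, -57, -47)
  ss <- assignSS(tr)
  cats <- collapseCategories(ss)
  expect_true(all(cats[ssCodes(ss) == "H"] == "alpha-helix"))
  expect_true(all(cats[ssCodes(ss) == "-"] == "coil"))
  expect_error(collapseCategories(ss, c(E = "beta-sheet")), "missing")
  # isolated bridges and 3-10 helix report as coil
  tab <- defaultSSCategoryTable()
  expect_identical(unname(tab[c("B", "G", "I")]), rep("coil", 3))
})

test_that("short chains warn and assign '-'", {
  sys <- peptideSystem("GG", data.frame(
    name = rep(c("N", "CA", "C", "O"), 2),
    element = rep(c("N", "C", "C", "O"), 2),
    chain = "A", resno = rep(c(105L, 106L), each = 4)), offset = 105L)
  xyz <- matrix(rnorm(24), 8, 3)
  expect_warning(ss <- assignSS(xyz, sys), "shorter than 3")
  expect_true(all(ssCodes(ss) == "-"))
})

test_that("secondary-structure statistics are normalized probabilities", {
  out <- makeTrajectory(list(list(kind = "coil", frames = 3),
                             list(kind = "sheet", frames = 3)),
                        nChains = 4, seed = 51, noise = 0.05)
  traj <- out$trajectory
  st <- ssStatistics(traj)
  expect_equal(sum(st$overall), 1, tolerance = 1e-12)
  expect_true(all(abs(rowSums(st$perResidue) - 1) < 1e-12))
  expect_true(all(st$perResidue >= 0 & st$perResidue <= 1))
  # a pure-helix ensemble is fully alpha-helix at core residues
  helix <- assembleState("helix", nChains = 2, seed = 52)
  sth <- ssStatistics(helix)
  expect_equal(unname(sth$perResidue["110", "alpha-helix"]), 1)
  # single-frame input gives probabilities in {0, 1}
  expect_true(all(sth$perResidue %in% c(0, 1)))
  expect_error(ssStatistics(traj, window = integer(0)), "window")
})

test_that("timelines recover the schedule switch point", {
  out <- makeTrajectory(list(list(kind = "coil", frames = 4),
                             list(kind = "sheet", frames = 4)),
                        nChains = 4, seed = 61, noise = 0.05)
  tl <- ssTimeline(out$trajectory)
  expect_equal(dim(tl), c(4 * 11, 8))
  sheet_frac <- colMeans(tl == "beta-sheet")
  expect_true(all(sheet_frac[1:4] == 0))
  expect_true(all(sheet_frac[5:8] > 0.5))
})
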