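test_that("atom counts match peptide stoichiometry", {
  expect_identical(countAtoms(TTR_SEQ), 172L)
  expect_identical(countAtoms("G"), 10L)   # glycine zwitterion C2H5NO2
  expect_identical(countAtoms("AA"), 23L)  # 13 + 13 - H2O
  expect_error(countAtoms("AXA"), "unknown residue")
  expect_error(countAtoms(""), "empty")
  # neutral termini have the same atom count as the zwitterion
  expect_identical(countAtoms(TTR_SEQ, "neutral"), 172L)
})

test_that("atom counting is additive up to one condensation water", {
  set.seed(101)
  aas <- names(OligoTraj:::.HEAVY_ATOMS)
  for (rep in 1:10) {
    s1 <- paste(sample(aas, sample(2:6, 1), replace = TRUE), collapse = "")
    s2 <- paste(sample(aas, sample(2:6, 1), replace = TRUE), collapse = "")
    expect_identical(countAtoms(paste0(s1, s2)),
                     countAtoms(s1) + countAtoms(s2) - 3L)
  }
})

test_that("residue rosters carry standard stoichiometry", {
  g <- residueComposition("G")
  expect_equal(nrow(g), 7L)
  a <- residueComposition("A")
  expect_equal(nrow(a), 10L)
  expect_true(all(c("N", "CA", "C", "O", "CB") %in% a$name))
  expect_error(residueComposition("X"), "unknown")
})

test_that("built chains have ideal backbone geometry", {
  ext <- buildPeptide(TTR_SEQ, -139, 135)
  sys <- trajectorySystem(ext)
  ca <- selectAtoms(sys, "calpha")
  expect_length(ca, 11L)
  x <- getFrame(ext, 1)
  dd <- sqrt(rowSums(diff(x[ca, ])^2))
  expect_true(all(abs(dd - 3.80) < 0.02))

  # helical rise of ~1.5 Angstrom per residue along the helix axis
  hel <- buildPeptide(TTR_SEQ, -57, -47)
  hca <- getFrame(hel, 1)[selectAtoms(trajectorySystem(hel), "calpha"), ]
  centered <- sweep(hca, 2, colMeans(hca))
  axis <- svd(centered)$v[, 1]
  proj <- centered %*% axis
  rise <- abs(proj[11] - proj[1]) / 10
  expect_equal(as.numeric(rise), 1.5, tolerance = 0.1)

  # proline has no amide hydrogen; the first residue has none either
  at <- atomData(sys)
  expect_false(any(at$name == "H" & at$resno == 113))  # P113
  expect_false(any(at$name == "H" & at$resno == 105))
  expect_equal(sum(at$name == "OXT"), 1L)
})

test_that("assembled states are deterministic in the seed", {
  a <- assembleState("coil", nChains = 3, noise = 0.2, seed = 111)
  b <- assembleState("coil", nChains = 3, noise = 0.2, seed = 111)
  expect_identical(a@coords, b@coords)
  c <- assembleState("coil", nChains = 3, noise = 0.2, seed = 112)
  expect_false(identical(a@coords, c@coords))
})

test_that("assembled sheets carry the promised hydrogen-bond registry", {
  tr <- assembleState("sheet", nChains = 2, seed = 113)
  hb <- detectHBonds(getFrame(tr, 1), trajectorySystem(tr))
  expect_gte(sum(hb$interchain), 2)
  gt <- groundTruthLabel(tr)
  expect_equal(gt$label, "single_sheet")
  expect_equal(gt$orientation, "antiparallel")
})

test_that("coil states keep chains at least 4 Angstrom apart", {
  tr <- assembleState("coil", nChains = 4, seed = 114)
  sys <- trajectorySystem(tr)
  xyz <- getFrame(tr, 1)
  at <- atomData(sys)
  for (a in 1:3) {
    for (b in (a + 1):4) {
      ia <- which(at$chain == LETTERS[a])
      ib <- which(at$chain == LETTERS[b])
      expect_gte(sqrt(min(OligoTraj:::.crossdist2(xyz[ia, ], xyz[ib, ]))), 4)
    }
  }
})

test_that("impossible geometries are rejected", {
  expect_error(assembleState("closed_barrel", nChains = 2), "at least 3")
  expect_error(assembleState("bilayer", nChains = 3), "layers")
  expect_error(assembleState("sheet", nChains = 1), "at least 2")
})

test_that("labelled pseudo-trajectories follow their schedule", {
  f <- withr::local_tempfile(fileext = ".pdb")
  out <- makeTrajectory(list(list(kind = "coil", frames = 4),
                             list(kind = "sheet", frames = 4)),
                        nChains = 2, seed = 115, noise = 0.1, path = f)
  expect_equal(nFrames(out$trajectory), 8L)
  expect_equal(out$groundTruth$kind, rep(c("coil", "sheet"), each = 4))
  expect_equal(out$groundTruth$label,
               rep(c("disordered", "single_sheet"), each = 4))
  expect_true(file.exists(f))
  sidecar <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(sidecar$seed, 115L)
  expect_equal(sidecar$frames$label, out$groundTruth$label)

  # regenerating with the same seed gives an identical file
  f2 <- withr::local_tempfile(fileext = ".pdb")
  makeTrajectory(list(list(kind = "coil", frames = 4),
                      list(kind = "sheet", frames = 4)),
                 nChains = 2, seed = 115, noise = 0.1, path = f2)
  expect_identical(readLines(f), readLines(f2))

  # single-state schedules are homogeneous
  out2 <- makeTrajectory(list(list(kind = "helix", frames = 3)),
                         nChains = 2, seed = 116)
  expect_equal(unique(out2$groundTruth$kind), "helix")
  expect_error(makeTrajectory(list(), nChains = 2, seed = 1), "empty")
})
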