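test_that("1D densities integrate to one", {
  set.seed(91)
  x <- rnorm(500)
  d <- pdf1d(x, bins = 25)
  widths <- diff(seq(min(x), max(x), length.out = 26))
  expect_equal(sum(d$density * widths), 1, tolerance = 1e-9)
  # constant series occupies a single bin
  dc <- pdf1d(rep(2, 10), bins = 5)
  expect_equal(sum(dc$count > 0), 1L)
  expect_error(pdf1d(numeric(0)), "empty")
})

test_that("free-energy landscapes follow -RT ln H", {
  # uniform occupancy: PMF identically zero on occupied bins
  x <- rep(1:4, each = 5)
  y <- rep(1:5, times = 4)
  l <- pmf2d(x, y, temperature = 310)
  occ <- probabilityMatrix(l) > 0
  expect_true(all(pmfMatrix(l)[occ] == 0))
  expect_true(all(is.infinite(pmfMatrix(l)[!occ])))
  expect_equal(sum(probabilityMatrix(l)), 1, tolerance = 1e-12)

  # counts 4 and 1 at 310 K: delta PMF = RT ln 4 = 3.5733 kJ/mol
  l2 <- pmf2d(c(1, 1, 1, 1, 2), c(1, 1, 1, 1, 1))
  pm <- pmfMatrix(l2)
  finite <- sort(pm[is.finite(pm)])
  expect_equal(finite[2] - finite[1], 8.314462e-3 * 310 * log(4),
               tolerance = 1e-9)
  expect_error(pmf2d(1:3, 1:4), "equal length")
})

test_that("PMF differences depend only on bin count ratios", {
  set.seed(92)
  for (rep in 1:10) {
    x <- sample(1:6, 400, replace = TRUE)
    y <- runif(400)
    l <- pmf2d(x, y, temperature = 310)
    H <- probabilityMatrix(l)
    pm <- pmfMatrix(l)
    occ <- which(H > 0)
    i <- sample(occ, 1); j <- sample(occ, 1)
    expect_equal(pm[i] - pm[j],
                 -8.314462e-3 * 310 * log(H[i] / H[j]),
                 tolerance = 1e-9)
  }
})

test_that("contact probability maps aggregate chains correctly", {
  # frozen ideal dimer sheet: contacted pairs at probability 1
  tr <- assembleState("sheet", nChains = 2, seed = 93)
  traj <- peptideTrajectory(trajectorySystem(tr),
                            list(getFrame(tr, 1), getFrame(tr, 1)))
  maps <- contactProbabilityMap(traj)
  expect_true(all(maps$interchain >= 0 & maps$interchain <= 1))
  expect_true(isSymmetric(maps$interchain))
  expect_true(any(maps$interchain == 1))
  expect_equal(dim(maps$interchain), c(11, 11))
  expect_equal(dim(maps$intrachain), c(11, 11))

  # far-apart coil chains: no interchain contacts at all
  coil <- assembleState("coil", nChains = 3, seed = 94)
  cmaps <- contactProbabilityMap(coil)
  expect_equal(sum(cmaps$interchain), 0)
  expect_error(contactProbabilityMap(coil, window = integer(0)), "empty")
})

test_that("interaction time series split interchain and intrachain counts", {
  # single chain: interchain identically zero
  single <- buildPeptide(TTR_SEQ, -57, -47)
  ts1 <- interactionTimeseries(single)
  expect_equal(ts1$hbInter, 0L)
  expect_equal(ts1$contactInter, 0L)
  expect_equal(ts1$hbTotal, ts1$hbIntra + ts1$hbInter)

  # ideal sheet frame: interchain H-bond count matches detectHBonds
  tr <- assembleState("sheet", nChains = 4, seed = 95)
  ts <- interactionTimeseries(tr)
  hb <- detectHBonds(getFrame(tr, 1), trajectorySystem(tr))
  expect_equal(ts$hbInter, sum(hb$interchain))
  expect_equal(ts$hbIntra, sum(!hb$interchain))

  # counts reproduce the generator schedule switch
  out <- makeTrajectory(list(list(kind = "coil", frames = 3),
                             list(kind = "sheet", frames = 3)),
                        nChains = 2, seed = 96, noise = 0.05)
  tss <- interactionTimeseries(out$trajectory)
  expect_true(all(tss$hbInter[1:3] == 0))
  expect_true(all(tss$hbInter[4:6] >= 2))
})

test_that("window overlap coefficient behaves as a distribution overlap", {
  expect_equal(histogramOverlap(c(1, 1, 2, 2), c(1, 2, 2, 2), bins = 2), 0.75)
  expect_equal(histogramOverlap(rep(1, 5), rep(10, 5), bins = 4), 0)
  expect_equal(histogramOverlap(1:10, 1:10, bins = 5), 1)

  out <- makeTrajectory(list(list(kind = "sheet", frames = 8)),
                        nChains = 2, seed = 97, noise = 0.1)
  traj <- out$trajectory
  ov <- convergenceOverlap(traj, 1:4, 5:8, "hbonds")
  expect_gte(ov, 0)
  expect_lte(ov, 1)
  # symmetry in the two windows
  expect_equal(convergenceOverlap(traj, 5:8, 1:4, "hbonds"), ov)
  expect_error(convergenceOverlap(traj, 1:4, 4:8), "disjoint")
  expect_error(convergenceOverlap(traj, integer(0), 5:8), "empty")
})

test_that("ion counts reproduce the published box setups", {
  expect_identical(ionCount(0.15, 4.757), 10L)
  expect_identical(ionCount(0.15, 5.873), 18L)
  expect_identical(ionCount(0.15, 7.060), 32L)
  expect_identical(ionCount(0, 5), 0L)
  expect_error(ionCount(-0.1, 5), ">= 0")
  expect_error(ionCount(0.15, 0), "> 0")
})

test_that("simulation plan totals accumulate run times", {
  plan <- ttrSimulationPlan()
  expect_equal(planTotals(plan), 31.5)
  expect_equal(planTotals(data.frame(timePerRun = 1.5, runs = 1)), 1.5)
  expect_equal(planTotals(plan[0, ]), 0)
  expect_equal(attr(plan, "saltConcentration"), 0.15)
})
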