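test_that("MLEM recovers an impulse with an exact-adjoint blur-free model", {
  ph <- airPointPhantom(n = c(15L, 15L, 11L), voxelMm = 10, value = 500)
  geom <- blurFreeGeometry(nAngles = 6L)
  spectra <- defaultSpectra()
  g <- projectPhantom(ph, spectra, geom)  # noiseless, non-integer is fine
  rec <- dosemReconstruct(g, ph, geom, nIters = 30L, nSubsets = 1L,
                          strayReference = 0)
  m <- activityMap(rec, "Th")
  ctr <- c(8, 8, 6)
  nb <- m[ctr[1] + (-1:1), ctr[2] + (-1:1), ctr[3] + (-1:1)]
  expect_gte(sum(nb) / sum(m), 0.95)
})

test_that("one-subset DOSEM is dual-isotope MLEM with monotone likelihood", {
  s <- tinySetup()
  g <- simulateProjections(s$sysmat, s$truth, seed = 61)
  rec <- dosemReconstruct(g, s$phantom, s$geometry, s$windows, s$detector,
                          s$spectra, nIters = 4L, nSubsets = 1L,
                          trackLogLik = TRUE)
  ll <- attr(rec, "logLik")
  expect_true(all(diff(ll) >= -1e-7 * pmax(abs(ll[-1]), 1)))
  # independent plain-R MLEM oracle, iterated with the same operators
  argsTh <- mewpdq:::.projArgs(s$phantom, s$geometry, s$windows, s$detector,
                               s$spectra$Th)
  argsRa <- mewpdq:::.projArgs(s$phantom, s$geometry, s$windows, s$detector,
                               s$spectra$Ra)
  n <- dim(voiLabels(s$phantom))
  psiW <- strayNoiseMeans(s$windows, 1L, s$geometry@acquisitionTimeS, 0.05)
  psiFull <- rep(psiW, each = prod(s$sysmat@projDim[1:3]))
  sensTh <- mewpdq:::.backward(rep(1, prod(s$sysmat@projDim)), argsTh)[[1]]
  sensRa <- mewpdq:::.backward(rep(1, prod(s$sysmat@projDim)), argsRa)[[1]]
  f0 <- max(sum(counts(g)) - sum(psiFull), 0) /
    (sum(sensTh) + sum(sensRa))
  fTh <- array(f0, n); fRa <- array(f0, n)
  for (it in 1:4) {
    mu <- as.numeric(mewpdq:::.forward(list(fTh), argsTh)) +
          as.numeric(mewpdq:::.forward(list(fRa), argsRa)) + psiFull
    r <- counts(g) / mu
    bTh <- mewpdq:::.backward(r, argsTh)[[1]]
    bRa <- mewpdq:::.backward(r, argsRa)[[1]]
    fTh <- ifelse(sensTh > 0, fTh * bTh / sensTh, 0)
    fRa <- ifelse(sensRa > 0, fRa * bRa / sensRa, 0)
  }
  expect_equal(activityMap(rec, "Th"), array(fTh, n), tolerance = 1e-12)
  expect_equal(activityMap(rec, "Ra"), array(fRa, n), tolerance = 1e-12)
})

test_that("DOSEM handles degenerate inputs per contract", {
  s <- tinySetup()
  zero <- rep(0, prod(s$sysmat@projDim))
  rec <- dosemReconstruct(zero, s$phantom, s$geometry, s$windows, s$detector,
                          s$spectra, nIters = 2L, nSubsets = 4L)
  expect_true(all(activityMap(rec, "Th") == 0))
  expect_true(all(activityMap(rec, "Ra") == 0))
  expect_error(dosemReconstruct(zero, s$phantom, s$geometry, s$windows,
                                s$detector, s$spectra, nSubsets = 3L),
               "divisible")
})

test_that("VOI means agree with a brute-force masked mean", {
  s <- tinySetup()
  labels <- voiLabels(s$phantom)
  # constant map: every region mean equals the constant
  rc <- new("VoxelRecon", mapTh = array(7, dim(labels)),
            mapRa = array(2, dim(labels)), voxelMm = s$phantom@voxelMm,
            nIters = 1L, nSubsets = 1L)
  m <- voiMeanUptake(rc, labels)
  expect_equal(unname(m@lambdaTh), rep(7, 4))
  expect_equal(unname(m@lambdaRa), rep(2, 4))
  # random map against direct masked averaging
  set.seed(71)
  mp <- array(runif(length(labels)), dim(labels))
  rc2 <- new("VoxelRecon", mapTh = mp, mapRa = mp,
             voxelMm = s$phantom@voxelMm, nIters = 1L, nSubsets = 1L)
  m2 <- voiMeanUptake(rc2, labels)
  for (k in 1:4)
    expect_equal(unname(m2@lambdaTh[k]), mean(mp[labels == k]),
                 tolerance = 1e-12)
})

test_that("GTM correction inverts the transfer matrix", {
  raw <- regionalUptakeValues(c(2, 2, 2, 2), c(1, 1, 1, 1),
                              names = c("a", "b", "c", "d"))
  idm <- diag(4)
  out <- gtmCorrect(raw, list(Th = idm, Ra = idm))
  expect_equal(unname(out$lambdaTh), rep(2, 4))
  out2 <- gtmCorrect(raw, list(Th = 2 * idm, Ra = 2 * idm))
  expect_equal(unname(out2$lambdaTh), rep(1, 4))
  expect_equal(unname(out2$lambdaRa), rep(0.5, 4))
  expect_false(out2$negative)
  expect_error(gtmCorrect(raw, list(Th = matrix(1, 4, 4), Ra = idm)),
               "singular")
})

test_that("matched-pipeline GTM recovers truth in a well-posed fixture", {
  # blur-free, angularly well-sampled fixture at the high-count limit:
  # the reconstruction is close to invertible, so the unit-VOI spread
  # functions and the correction recover every regional mean
  ph <- makePelvicPhantom(grid = phantomGrid(c(24L, 24L, 16L), 11.8))
  geom <- scannerGeometry(nAngles = 12L, intrinsicFwhmMm = 0,
                          collimatorSlopeMmPerCm = 0, scatterFraction = 0,
                          energyGroupKeV = 20, nDepthBands = 2L)
  geom <- calibrateSensitivity(ph, geom, targetTotalCounts = 2e7)
  sm <- buildSystemMatrix(ph, geom)
  truth <- regionalUptake(ph)
  gN <- as.numeric(systemMatrix(sm, "Th") %*% truth@lambdaTh +
                   systemMatrix(sm, "Ra") %*% truth@lambdaRa) + strayMeans(sm)
  bl <- baselineQuantify(gN, sm, ph, geom, nIters = 100L, nSubsets = 4L)
  expect_equal(unname(bl$gtm$lambdaTh), unname(truth@lambdaTh),
               tolerance = 0.10)
  expect_equal(unname(bl$gtm$lambdaRa), unname(truth@lambdaRa),
               tolerance = 0.10)
})

test_that("GTM reduces the blur-driven lesion bias of the raw VOI means", {
  s <- tinySetup()
  # noiseless expected data (high-count limit) under the full HEGP-like blur
  gN <- as.numeric(systemMatrix(s$sysmat, "Th") %*% s$truth@lambdaTh +
                   systemMatrix(s$sysmat, "Ra") %*% s$truth@lambdaRa) +
    strayMeans(s$sysmat)
  bl <- baselineQuantify(gN, s$sysmat, s$phantom, s$geometry, s$windows,
                         s$detector, s$spectra, nIters = 16L, nSubsets = 4L)
  tru <- s$truth@lambdaTh[["lesion"]]
  # raw means lose a large fraction of the lesion to spill-out ...
  expect_lt(bl$dosem@lambdaTh[["lesion"]], 0.8 * tru)
  # ... the correction moves both isotopes' lesion estimates toward truth
  expect_lt(abs(bl$gtm$lambdaTh[["lesion"]] - tru),
            abs(bl$dosem@lambdaTh[["lesion"]] - tru))
  truRa <- s$truth@lambdaRa[["lesion"]]
  expect_lt(abs(bl$gtm$lambdaRa[["lesion"]] - truRa),
            abs(bl$dosem@lambdaRa[["lesion"]] - truRa))
  # transfer-matrix structure: self-recovery below one (spill-out) and a
  # positive bone-to-lesion spill under the pelvic geometry
  for (Om in bl$omega) {
    expect_true(all(diag(Om) > 0 & diag(Om) <= 1))
    expect_gt(Om["lesion", "bone"], 0)
  }
})
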