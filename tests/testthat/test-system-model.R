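test_that("point source in air without blur matches the analytic oracle", {
  ph <- airPointPhantom(value = 1000)
  geom <- blurFreeGeometry(nAngles = 6L)
  windows <- defaultEnergyWindows()
  det <- detectorEnergyModel()
  th <- loadBuiltinSpectrum("Th227")
  p <- projectEmissionMap(activityMap(ph, "Th"), ph, th, geom, windows, det)
  # analytic total: activity * voxel volume * summed window weights * time
  W <- windowDetectionWeights(th, windows, det)
  expected <- 1000 * (10 / 10)^3 * sum(W) * geom@sensitivityScale *
    geom@acquisitionTimeS
  expect_equal(sum(p), expected, tolerance = 1e-6)
  # counts concentrated in the geometrically matching (centre) bin per view
  arr <- array(p, dim = c(21, 15, 6, 4))
  for (a in 1:6) {
    sl <- arr[, , a, ]
    expect_equal(sum(sl[11, 8, ]), sum(sl), tolerance = 1e-12)
  }
})

test_that("projector is linear, time-scaling, and attenuation-monotone", {
  s <- tinySetup()
  ph <- s$phantom
  a1 <- activityMap(ph, "Th")
  set.seed(5)
  a2 <- a1 * 0
  a2[voiLabels(ph) > 0] <- runif(sum(voiLabels(ph) > 0), 0, 100)
  pr <- function(a, geom = s$geometry, phan = ph)
    projectEmissionMap(a, phan, s$spectra$Th, geom, s$windows, s$detector)
  p1 <- pr(a1); p2 <- pr(a2); p12 <- pr(a1 + a2)
  expect_equal(p12, p1 + p2, tolerance = 1e-10)
  expect_true(all(p1 >= 0))
  # zero activity projects to zero
  expect_true(all(pr(a1 * 0) == 0))
  # doubling acquisition time doubles every expected count
  g2 <- s$geometry; g2@acquisitionTimeS <- 2 * s$geometry@acquisitionTimeS
  expect_equal(pr(a1, g2), 2 * p1, tolerance = 1e-12)
  # increasing attenuation anywhere never increases any expected count
  denser <- ph
  denser@muSoft <- ph@muSoft * 1.5
  expect_true(all(pr(a1, phan = denser) <= p1 + 1e-12 * max(p1)))
  # non-finite activity rejected
  bad <- a1; bad[1] <- NaN
  expect_error(pr(bad), "non-finite")
})

test_that("regional system matrix obeys superposition and layout", {
  s <- tinySetup()
  sm <- s$sysmat
  expect_identical(dim(systemMatrix(sm, "Th")),
                   c(as.integer(prod(sm@projDim)), 4L))
  expect_true(all(systemMatrix(sm, "Th") >= 0))
  expect_true(all(colSums(systemMatrix(sm, "Th")) > 0))
  expect_true(all(colSums(systemMatrix(sm, "Ra")) > 0))
  # matched-model identity: H lambda equals the voxel-mode projection
  lam <- s$truth
  voi <- as.numeric(systemMatrix(sm, "Th") %*% lam@lambdaTh +
                    systemMatrix(sm, "Ra") %*% lam@lambdaRa)
  vox <- projectPhantom(s$phantom, s$spectra, s$geometry, s$windows,
                        s$detector)
  expect_equal(voi, vox, tolerance = 1e-10)
  # empty VOI is reported by name
  broken <- s$phantom
  broken@activityTh[broken@voiLabels == 4L] <- 0
  broken@activityRa[broken@voiLabels == 4L] <- 0
  broken@voiLabels[broken@voiLabels == 4L] <- 2L
  expect_error(buildSystemMatrix(broken, s$geometry, s$windows, s$detector,
                                 s$spectra), "lesion")
})

test_that("stray-noise means scale with window width and acquisition time", {
  w <- defaultEnergyWindows()
  expect_true(all(strayNoiseMeans(w, 10, 1800, referenceMean = 0) == 0))
  # two windows of equal width share one stray mean
  w2 <- energyWindows(low = c(100, 200), high = c(130, 230))
  psi <- strayNoiseMeans(w2, 5, 600, referenceMean = 0.4,
                         referenceWindow = 1L)
  expect_equal(unique(psi), 0.4)
  # 30 min acquisition triples the 10-min reference in the anchor window
  psi3 <- strayNoiseMeans(w, 3, 1800, referenceMean = 0.05,
                          referenceWindow = 3L)
  expect_equal(unique(psi3[6 + 1:3]), 0.15)  # window-3 block (Ms = 3)
  # width proportionality between windows
  widths <- w@high - w@low
  blocks <- matrix(psi3, nrow = 3)
  expect_equal(blocks[1, ] / blocks[1, 3], widths / widths[3],
               tolerance = 1e-12)
  expect_error(strayNoiseMeans(w, 3, 1800, referenceWindow = 9L),
               "out of range")
})

test_that("Poisson simulation is seeded, mean-faithful and nonnegative", {
  sm <- toySysmat(seed = 2)
  lam <- regionalUptakeValues(c(3, 1), c(2, 4))
  g1 <- simulateProjections(sm, lam, seed = 99)
  g2 <- simulateProjections(sm, lam, seed = 99)
  expect_identical(counts(g1), counts(g2))
  expect_true(all(counts(g1) >= 0))
  expect_true(all(counts(g1) == round(counts(g1))))
  # zero uptake and zero stray means give all-zero counts
  sm0 <- toySysmat(seed = 2, psi = c(0, 0))
  z <- simulateProjections(sm0, regionalUptakeValues(c(0, 0), c(0, 0)), 1)
  expect_true(all(counts(z) == 0))
  # Monte-Carlo moment oracle: sample mean of one bin within 3 SE
  mu <- as.numeric(sm@HTh %*% lam@lambdaTh + sm@HRa %*% lam@lambdaRa) + sm@psi
  draws <- vapply(1:10000, function(i)
    counts(simulateProjections(sm, lam, seed = i))[1], numeric(1))
  se <- sqrt(mu[1] / 10000)
  expect_lt(abs(mean(draws) - mu[1]), 3 * se)
})

test_that("sensitivity calibration hits the requested count level", {
  s <- tinySetup()
  tot <- sum(projectPhantom(s$phantom, s$spectra, s$geometry, s$windows,
                            s$detector))
  expect_equal(tot, 2e5, tolerance = 1e-10)
})
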