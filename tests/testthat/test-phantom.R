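test_that("standard phantom hits target totals and lesion volume", {
  # fine grid so the voxelized sphere volume is within discretization error
  ph <- makePelvicPhantom(grid = phantomGrid(c(128L, 128L, 96L), 2.21))
  vv <- (2.21 / 10)^3
  tot <- standardTotalActivity()
  expect_equal(sum(activityMap(ph, "Th")) * vv, tot[["Th"]],
               tolerance = 1e-3)
  expect_equal(sum(activityMap(ph, "Ra")) * vv, tot[["Ra"]],
               tolerance = 1e-3)
  lesVol <- sum(voiLabels(ph) == 4L) * vv  # mL
  expect_equal(lesVol, pi / 6 * 3.375^3, tolerance = 0.02)
  # regional means reproduce the requested uptake exactly
  expect_equal(uptakeVector(phantomRegionalMeans(ph)),
               uptakeVector(regionalUptake(ph)), tolerance = 1e-12)
  # structural invariants
  expect_true(all(voiLabels(ph)[activityMap(ph, "Th") > 0] > 0))
  expect_true(all(muMap(ph) >= 0))
})

test_that("zero uptake yields identically zero activity maps", {
  up <- regionalUptakeValues(rep(0, 4), rep(0, 4))
  ph <- makePelvicPhantom(grid = tinyGrid(), uptake = up)
  expect_true(all(activityMap(ph, "Th") == 0))
  expect_true(all(activityMap(ph, "Ra") == 0))
})

test_that("lesion overflowing the bone support is rejected with a count", {
  expect_error(
    makePelvicPhantom(grid = tinyGrid(), lesionDiameterMm = 120),
    "not.*fully inside the bone support")
  expect_error(
    makePelvicPhantom(grid = tinyGrid(), lesionCenterMm = c(0, 0, 0),
                      lesionDiameterMm = 20),
    "voxels overflow")
})

test_that("lumpy heterogeneity preserves regional means at study parameters", {
  ph <- makePelvicPhantom(grid = tinyGrid())
  lumpy <- list(background = c(380, 23), gut = c(140, 16), lesion = c(490, 2))
  out <- ph
  for (rn in names(lumpy))
    out <- applyLumpyHeterogeneity(out, rn, lumpy[[rn]][1], lumpy[[rn]][2],
                                   seed = 11)
  expect_true(all(activityMap(out, "Th") >= 0))
  expect_true(all(activityMap(out, "Ra") >= 0))
  # brute-force voxel-averaging oracle: means match the design exactly
  m <- phantomRegionalMeans(out)
  expect_equal(uptakeVector(m), uptakeVector(regionalUptake(ph)),
               tolerance = 1e-10)
  # the texture is genuinely heterogeneous
  bg <- activityMap(out, "Th")[voiLabels(out) == 1L]
  expect_gt(sd(bg) / mean(bg), 0.01)
  # zero-lump draw leaves the region homogeneous (documented fallback)
  hom <- applyLumpyHeterogeneity(ph, "gut", 0, 16, seed = 3)
  expect_identical(activityMap(hom, "Th"), activityMap(ph, "Th"))
  # a second application on a now-heterogeneous region is refused
  expect_error(applyLumpyHeterogeneity(out, "gut", 140, 16, seed = 4),
               "homogeneous")
})

test_that("mixture model is linear and leaves regional means invariant", {
  ph <- makePelvicPhantom(grid = tinyGrid())
  het <- applyLumpyHeterogeneity(ph, "background", 380, 23, seed = 21)
  expect_identical(activityMap(mixHeterogeneity(het, ph, 0), "Th"),
                   activityMap(ph, "Th"))
  expect_identical(activityMap(mixHeterogeneity(het, ph, 1), "Th"),
                   activityMap(het, "Th"))
  for (W in c(0.1, 0.2, 0.3, 0.4, 0.8)) {
    mix <- mixHeterogeneity(het, ph, W)
    expect_equal(uptakeVector(phantomRegionalMeans(mix)),
                 uptakeVector(regionalUptake(ph)), tolerance = 1e-12)
  }
  other <- makePelvicPhantom(grid = phantomGrid(c(24L, 24L, 18L), 11.8))
  expect_error(mixHeterogeneity(het, other, 0.5), "grid")
})

test_that("VIT population sampling is reproducible and respects truncation", {
  cfg <- vitConfig(grid = tinyGrid(), bodyScaleRange = c(0.9, 1.1))
  p1 <- sampleVitPopulation(12, seed = 42, config = cfg)
  p2 <- sampleVitPopulation(12, seed = 42, config = cfg)
  expect_identical(serialize(p1, NULL), serialize(p2, NULL))
  expect_true(all(p1$info$diameterMm >= cfg$minDiameterMm))
  expect_true(all(p1$info$diameterMm <= cfg$maxDiameterMm))
  for (ph in p1$patients) {
    expect_true(all(uptakeVector(regionalUptake(ph)) >= 0))
    expect_true(all(voiLabels(ph)[activityMap(ph, "Ra") > 0] > 0))
    expect_true(sum(voiLabels(ph) == 4L) > 0)  # lesion never empty
  }
  # sample mean diameter near the population mean (diameter sampling only)
  big <- sampleVitPopulation(60, seed = 7, config = cfg)
  expect_lt(abs(mean(big$info$diameterMm) - 33.75), 4)
})

test_that("rigid misregistration resamples mass-conservatively, labels stale", {
  ph <- makePelvicPhantom(grid = tinyGrid())
  expect_identical(applyRigidMisregistration(ph, c(0, 0), 0), ph)
  moved <- applyRigidMisregistration(ph, shiftVoxels = c(1, 1),
                                     rotationDeg = 2)
  # labels deliberately untouched (stale VOI design)
  expect_identical(voiLabels(moved), voiLabels(ph))
  # total activity conserved to interpolation tolerance
  expect_equal(sum(activityMap(moved, "Th")), sum(activityMap(ph, "Th")),
               tolerance = 5e-3)
  expect_equal(sum(muMap(moved)), sum(muMap(ph)), tolerance = 5e-3)
  # a 9-voxel shift along x is supported on a fine grid with lateral margin
  big <- makePelvicPhantom(grid = phantomGrid(c(144L, 144L, 52L), 2.21))
  shifted <- applyRigidMisregistration(big, shiftVoxels = c(9, 0))
  expect_equal(sum(activityMap(shifted, "Ra")), sum(activityMap(big, "Ra")),
               tolerance = 5e-3)
  # clipping the body at the boundary is an error
  expect_error(applyRigidMisregistration(ph, shiftVoxels = c(20, 0)),
               "clips")
})
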