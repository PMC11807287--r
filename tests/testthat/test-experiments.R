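testCfg <- function(...) experimentConfig("test", methods = "mewpdq", ...)

test_that("convergence study records the protocol grid and is reproducible", {
  cfg <- testCfg(emIters = 300L)
  res <- runConvergenceStudy(cfg, diameters = c(25, 35))
  expect_true(all(res$errors$iteration %% 50 == 0))
  expect_lte(res$stableIteration, 1500)
  expect_setequal(unique(res$errors$diameter), c(25, 35))
  res2 <- runConvergenceStudy(cfg, diameters = c(25, 35))
  expect_identical(res$errors, res2$errors)
  expect_identical(res$stableIteration, res2$stableIteration)
})

test_that("sweeps cover the study conditions and report merit plus CRLB", {
  cfg <- testCfg(nRealizations = 2L, emIters = 200L)
  res <- runSweep("th_ra_ratio", cfg, values = c(10, 1))
  expect_setequal(unique(res$merit$value), c(10, 1))
  expect_identical(nrow(res$merit), 16L)  # 2 conditions x 8 cells
  expect_true(all(res$crlb$crlbNsd > 0))
  # LBUR sweep scales only the lesion ratio; the others stay at standard
  resL <- runSweep("lbur", cfg, values = 3)
  expect_identical(unique(resL$merit$value), 3)
  ratios <- standardUptakeRatios()
  ph <- makePelvicPhantom(grid = cfg$grid, uptakeRatios = local({
    r <- ratios; r[, "lesion"] <- r[, "bone"] * 3; r
  }))
  up <- regionalUptake(ph)
  expect_equal(up@lambdaTh[["lesion"]] / up@lambdaTh[["bone"]], 3,
               tolerance = 1e-9)
  expect_equal(up@lambdaTh[["gut"]] / up@lambdaTh[["bone"]], 100 / 30,
               tolerance = 1e-9)
  expect_error(runSweep("contrast", cfg), "arg")
})

test_that("virtual imaging trial emits ensemble metrics with provenance", {
  cfg <- testCfg(nPatients = 3L, emIters = 200L)
  res <- runVit(cfg)
  expect_identical(nrow(res$merit), 8L)  # 4 regions x 2 isotopes
  expect_true(all(c("ensembleNb", "absEnsembleNb", "ensembleNrmse") %in%
                  names(res$merit)))
  expect_identical(dim(res$patientErrors), c(3L, 8L))
  expect_true(nzchar(res$manifest$configHash))
  expect_identical(res$manifest$nPatients, 3L)
  # exact reproducibility from (config, seed)
  res2 <- runVit(cfg)
  expect_identical(res$merit, res2$merit)
})

test_that("heterogeneity at W = 0 reproduces the homogeneous data bitwise", {
  s <- tinySetup()
  het <- applyLumpyHeterogeneity(s$phantom, "lesion", 490, 2, seed = 5)
  mix0 <- mixHeterogeneity(het, s$phantom, 0)
  g0 <- simulateProjectionsVoxel(mix0, s$geometry, s$windows, s$detector,
                                 s$spectra, seed = 77)
  gh <- simulateProjectionsVoxel(s$phantom, s$geometry, s$windows,
                                 s$detector, s$spectra, seed = 77)
  expect_identical(counts(g0), counts(gh))
})

test_that("robustness drivers honor the stale-VOI mismatch design", {
  cfg <- testCfg(nRealizations = 1L, nHetPatients = 1L, emIters = 150L,
                 hetW = c(0, 0.4), shiftsX = 2, shiftsY = numeric(0),
                 rotationsDeg = numeric(0))
  het <- runRobustness("heterogeneity", cfg)
  expect_setequal(unique(het$merit$W), c(0, 0.4))
  expect_true(het$manifest$staleVoi)
  mis <- runRobustness("misregistration", cfg)
  expect_identical(unique(mis$merit$shiftX), 2)
  expect_identical(nrow(mis$merit), 8L)
})
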