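# Shared fixtures, built once per test run and memoised.

.fx <- new.env(parent = emptyenv())

tinyGrid <- function() phantomGrid(c(32L, 32L, 24L), 8.85)

# standard tiny imaging setup: phantom + calibrated geometry + system matrix
tinySetup <- function() {
  if (is.null(.fx$tiny)) {
    ph <- makePelvicPhantom(grid = tinyGrid())
    geom <- scannerGeometry(nAngles = 8L, energyGroupKeV = 20, nDepthBands = 4L)
    geom <- calibrateSensitivity(ph, geom)
    sm <- buildSystemMatrix(ph, geom)
    .fx$tiny <- list(phantom = ph, geometry = geom,
                     windows = defaultEnergyWindows(),
                     detector = detectorEnergyModel(),
                     spectra = defaultSpectra(),
                     sysmat = sm, truth = regionalUptake(ph))
  }
  .fx$tiny
}

# phantom in air (no attenuation) with a single hot voxel at the grid centre;
# grid dimensions odd so the centre voxel is a rotation fixed point
airPointPhantom <- function(n = c(21L, 21L, 15L), voxelMm = 10,
                            value = 1000) {
  labels <- array(0L, dim = n)
  act <- array(0, dim = n)
  ctr <- (n + 1) %/% 2
  labels[ctr[1], ctr[2], ctr[3]] <- 1L
  act[ctr[1], ctr[2], ctr[3]] <- value
  zero <- array(0, dim = n)
  new("Phantom", voxelMm = voxelMm, voiLabels = labels, voiNames = "source",
      muSoft = zero, muBone = zero, activityTh = act, activityRa = zero,
      uptake = regionalUptakeValues(value, 0, names = "source"))
}

blurFreeGeometry <- function(nAngles = 6L)
  scannerGeometry(nAngles = nAngles, intrinsicFwhmMm = 0,
                  collimatorSlopeMmPerCm = 0, scatterFraction = 0)

# small abstract system-matrix fixture with integer entries (so noiseless
# data H lambda + psi are valid integer counts); full column rank for
# generic draws
toySysmat <- function(seed = 1, Ms = 6L, nW = 2L, K = 2L, psi = c(1, 2)) {
  set.seed(seed)
  M <- Ms * nW
  HTh <- matrix(as.numeric(sample(0:9, M * K, replace = TRUE)), M, K)
  HRa <- matrix(as.numeric(sample(0:9, M * K, replace = TRUE)), M, K)
  HTh[1, ] <- HTh[1, ] + 1  # avoid zero columns
  HRa[2, ] <- HRa[2, ] + 1
  new("SystemMatrixSet", HTh = HTh, HRa = HRa,
      psi = rep(psi, each = Ms), projDim = c(Ms, 1L, 1L, nW),
      voiNames = paste0("V", seq_len(K)),
      windows = energyWindows(low = seq_len(nW) * 100,
                              high = seq_len(nW) * 100 + 50),
      meta = list())
}

# single-bin fixture: one isotope active (HRa column zero)
singleBinSysmat <- function(h = 2, psi = 1) {
  new("SystemMatrixSet", HTh = matrix(h), HRa = matrix(0),
      psi = psi, projDim = c(1L, 1L, 1L, 1L), voiNames = "V1",
      windows = energyWindows(100, 150), meta = list())
}
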