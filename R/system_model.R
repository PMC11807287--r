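# Simplified attenuated parallel-beam SPECT system model: forward projection,
# regional system matrices, stray-radiation noise and Poisson data simulation.
#
# Physics: per-energy-group attenuated line integrals (attenuation scaled to
# each group's energy through the bundled mass-attenuation table),
# distance-dependent Gaussian collimator + intrinsic blur applied in depth
# bands, exact per-line Gaussian energy-window detection weights, and an
# optional broad-Gaussian scatter surrogate added per window.  Projection
# bins are congruent with the phantom grid (nu = ny, nv = nz, bin size =
# voxel size); rows are ordered u, v, angle, window (window-major blocks).

#' Construct the scanner geometry
#'
#' Defaults model a dual-head system with a high-energy general-purpose
#' collimator: 60 views over 360 degrees, 30 min acquisition, 3.9 mm
#' intrinsic resolution, 1.6 mm FWHM per cm collimator slope, 200 mm radius
#' of rotation.  \code{sensitivityScale} is the count-level calibration
#' constant; see \code{\link{calibrateSensitivity}}.
#'
#' @param nAngles Number of views over 360 degrees.
#' @param acquisitionTimeS Total acquisition time (s).
#' @param intrinsicFwhmMm Intrinsic detector resolution (mm FWHM).
#' @param collimatorSlopeMmPerCm Collimator blur slope (mm FWHM per cm).
#' @param radiusMm Radius of rotation (mm).
#' @param sensitivityScale Detection-efficiency calibration constant.
#' @param scatterFraction Scatter-to-primary fraction per window (recycled).
#' @param scatterFwhmMm Scatter surrogate blur FWHM (mm).
#' @param nDepthBands Depth bands sharing one blur kernel.
#' @param energyGroupKeV Energy-group pooling width (keV; 0 = per line).
#' @return A \code{\link{ScannerGeometry-class}}.
#' @export
scannerGeometry <- function(nAngles = 60L, acquisitionTimeS = 1800,
                            intrinsicFwhmMm = 3.9,
                            collimatorSlopeMmPerCm = 1.6,
                            radiusMm = 200, sensitivityScale = 1,
                            scatterFraction = c(0.30, 0.15, 0.10, 0.08),
                            scatterFwhmMm = 50, nDepthBands = 8L,
                            energyGroupKeV = 10) {
  new("ScannerGeometry", nAngles = as.integer(nAngles),
      acquisitionTimeS = acquisitionTimeS, intrinsicFwhmMm = intrinsicFwhmMm,
      collimatorSlopeMmPerCm = collimatorSlopeMmPerCm, radiusMm = radiusMm,
      sensitivityScale = sensitivityScale, scatterFraction = scatterFraction,
      scatterFwhmMm = scatterFwhmMm, nDepthBands = as.integer(nDepthBands),
      energyGroupKeV = energyGroupKeV)
}

#' Bundled spectra of the two isotopes
#' @param intensityFloor Passed to \code{\link{loadBuiltinSpectrum}}.
#' @return List with elements \code{Th} and \code{Ra}.
#' @export
defaultSpectra <- function(intensityFloor = 1e-4)
  list(Th = loadBuiltinSpectrum("Th227", intensityFloor),
       Ra = loadBuiltinSpectrum("Ra223chain", intensityFloor))

.gaussKernel <- function(sigmaBins, cut = 4) {
  if (sigmaBins < 1e-6) return(1)
  h <- max(1L, ceiling(cut * sigmaBins))
  k <- exp(-(-h:h)^2 / (2 * sigmaBins^2))
  k / sum(k)
}

# depth-band blur kernels and band assignment for the rotated x axis
.blurPlan <- function(nx, voxelMm, geometry) {
  nB <- min(geometry@nDepthBands, nx)
  bandOfX <- as.integer(floor((seq_len(nx) - 1) * nB / nx))
  cx <- (nx + 1) / 2
  kernels <- vector("list", nB)
  for (b in seq_len(nB)) {
    xs <- which(bandOfX == b - 1L)
    xmid <- mean(xs)
    d <- max(geometry@radiusMm + (cx - xmid) * voxelMm, 0)  # mm to collimator
    fwhm <- sqrt(geometry@intrinsicFwhmMm^2 +
                 (geometry@collimatorSlopeMmPerCm * d / 10)^2)
    kernels[[b]] <- .gaussKernel(fwhm / (2 * sqrt(2 * log(2))) / voxelMm)
  }
  list(kernels = kernels, bandOfX = bandOfX)
}

.viewAngles <- function(nAngles) seq(0, 2 * pi, length.out = nAngles + 1)[seq_len(nAngles)]

# shared argument assembly for the compiled projector
.projArgs <- function(phantom, geometry, windows, detector, spectrum) {
  sm <- spectralModel(spectrum, windows, detector, geometry@energyGroupKeV)
  n <- dim(phantom@voiLabels)
  bp <- .blurPlan(n[1], phantom@voxelMm, geometry)
  nW <- length(windows@low)
  sf <- rep_len(geometry@scatterFraction, nW)
  sker <- .gaussKernel(geometry@scatterFwhmMm / (2 * sqrt(2 * log(2))) /
                       phantom@voxelMm, cut = 3)
  list(muS = phantom@muSoft, muB = phantom@muBone, dims = as.integer(n),
       voxelMm = phantom@voxelMm, angles = .viewAngles(geometry@nAngles),
       sSoft = sm$sSoft, sBone = sm$sBone, winW = sm$winW,
       kernels = bp$kernels, bandOfX = bp$bandOfX,
       scatterKernel = as.numeric(sker), scatterFrac = sf,
       scale = geometry@sensitivityScale *
         (geometry@acquisitionTimeS / geometry@nAngles) *
         (phantom@voxelMm / 10)^3)
}

.forward <- function(actList, args) {
  for (a in actList)
    if (any(!is.finite(a))) stop("non-finite values in activity map")
  out <- cpp_forward_project(actList, args$muS, args$muB, args$dims,
                             args$voxelMm, args$angles, args$sSoft, args$sBone,
                             args$winW, args$kernels, args$bandOfX,
                             args$scatterKernel, args$scatterFrac)
  out * args$scale
}

# adjoint of .forward; projList is a list of M-vectors, returns a list of
# voxel cubes
.backward <- function(projList, args) {
  if (!is.list(projList)) projList <- list(projList)
  projList <- lapply(projList, as.numeric)
  out <- cpp_back_project(projList, args$dims, args$muS, args$muB,
                          args$voxelMm, args$angles, args$sSoft, args$sBone,
                          args$winW, args$kernels, args$bandOfX,
                          args$scatterKernel, args$scatterFrac)
  nv <- prod(args$dims)
  lapply(seq_along(projList), function(m)
    array(out[(m - 1) * nv + seq_len(nv)] * args$scale, dim = args$dims))
}

#' Project a single-isotope emission map
#'
#' Expected (noise-free) counts in every spatial bin and energy window for a
#' voxel activity map of one isotope, given the phantom's attenuation.
#'
#' @param activity 3D activity map (Bq/mL) on the phantom grid.
#' @param phantom \code{Phantom} supplying the attenuation maps and grid.
#' @param spectrum \code{LineSpectrum} of the isotope.
#' @param geometry \code{ScannerGeometry}.
#' @param windows \code{EnergyWindows}.
#' @param detector \code{DetectorEnergyModel}.
#' @return M-vector of expected counts, M = ny*nz*nAngles*nWindows, ordered
#'   u, v, angle, window.
#' @export
projectEmissionMap <- function(activity, phantom, spectrum,
                               geometry = scannerGeometry(),
                               windows = defaultEnergyWindows(),
                               detector = detectorEnergyModel()) {
  if (!identical(dim(activity), dim(phantom@voiLabels)))
    stop("activity map does not share the phantom grid")
  args <- .projArgs(phantom, geometry, windows, detector, spectrum)
  as.numeric(.forward(list(activity), args))
}

#' Project both isotope maps of a phantom
#'
#' Sum of the per-isotope expected projections (voxel-mode forward model).
#'
#' @param phantom \code{Phantom}.
#' @param spectra List with \code{Th} and \code{Ra} \code{LineSpectrum}s.
#' @inheritParams projectEmissionMap
#' @return M-vector of expected counts.
#' @export
projectPhantom <- function(phantom, spectra = defaultSpectra(),
                           geometry = scannerGeometry(),
                           windows = defaultEnergyWindows(),
                           detector = detectorEnergyModel()) {
  projectEmissionMap(phantom@activityTh, phantom, spectra$Th, geometry,
                     windows, detector) +
    projectEmissionMap(phantom@activityRa, phantom, spectra$Ra, geometry,
                       windows, detector)
}

#' Stray-radiation noise means
#'
#' The stray-noise mean is constant across the spatial bins of a window and
#' proportional to the window width; it is anchored at a reference mean
#' measured in one window over a reference time (blank-scan convention:
#' window 3, 10 minutes) and scaled linearly with the acquisition time.
#'
#' @param windows \code{EnergyWindows}.
#' @param nSpatialBins Number of spatial bins Ms (per window).
#' @param acquisitionTimeS Acquisition time (s).
#' @param referenceMean Mean stray counts per bin in the reference window
#'   over \code{referenceTimeS}.
#' @param referenceWindow Index of the reference window.
#' @param referenceTimeS Reference scan duration (s).
#' @return M-vector (window-major blocks) of stray means.
#' @export
strayNoiseMeans <- function(windows, nSpatialBins, acquisitionTimeS,
                            referenceMean = 0.05, referenceWindow = 3L,
                            referenceTimeS = 600) {
  stopifnot(referenceMean >= 0)
  widths <- windows@high - windows@low
  if (any(widths <= 0)) stop("window widths must be positive")
  if (referenceWindow < 1 || referenceWindow > length(widths))
    stop("referenceWindow out of range")
  perWindow <- referenceMean * (widths / widths[referenceWindow]) *
    (acquisitionTimeS / referenceTimeS)
  rep(perWindow, each = nSpatialBins)
}

#' Build the regional system matrices
#'
#' Column (k) of each isotope's matrix is the noise-free expected projection
#' of unit activity concentration (1 Bq/mL) confined to VOI k — expected
#' counts per unit regional uptake.  The build is deterministic (analytic
#' expectation, no Monte-Carlo variance).
#'
#' @param phantom \code{Phantom} with non-empty VOIs.
#' @param geometry \code{ScannerGeometry}.
#' @param windows \code{EnergyWindows}.
#' @param detector \code{DetectorEnergyModel}.
#' @param spectra List with \code{Th} and \code{Ra} spectra.
#' @param strayReference,strayReferenceWindow,strayReferenceTimeS Stray-noise
#'   anchor passed to \code{\link{strayNoiseMeans}}.
#' @return A \code{\link{SystemMatrixSet-class}}.
#' @export
buildSystemMatrix <- function(phantom, geometry = scannerGeometry(),
                              windows = defaultEnergyWindows(),
                              detector = detectorEnergyModel(),
                              spectra = defaultSpectra(),
                              strayReference = 0.05,
                              strayReferenceWindow = 3L,
                              strayReferenceTimeS = 600) {
  K <- nRegions(phantom)
  masks <- vector("list", K)
  for (k in seq_len(K)) {
    m <- array(0, dim = dim(phantom@voiLabels))
    sel <- phantom@voiLabels == k
    if (!any(sel)) stop("VOI ", k, " (", phantom@voiNames[k], ") is empty")
    m[sel] <- 1
    masks[[k]] <- m
  }
  n <- dim(phantom@voiLabels)
  cols <- function(spectrum) {
    args <- .projArgs(phantom, geometry, windows, detector, spectrum)
    out <- .forward(masks, args)
    matrix(out, ncol = K, dimnames = list(NULL, phantom@voiNames))
  }
  HTh <- cols(spectra$Th)
  HRa <- cols(spectra$Ra)
  nW <- length(windows@low)
  projDim <- as.integer(c(n[2], n[3], geometry@nAngles, nW))
  Ms <- prod(projDim[1:3])
  psi <- strayNoiseMeans(windows, Ms, geometry@acquisitionTimeS,
                         strayReference, strayReferenceWindow,
                         strayReferenceTimeS)
  new("SystemMatrixSet", HTh = HTh, HRa = HRa, psi = psi, projDim = projDim,
      voiNames = phantom@voiNames, windows = windows,
      meta = list(voxelMm = phantom@voxelMm, gridDim = n,
                  nAngles = geometry@nAngles,
                  acquisitionTimeS = geometry@acquisitionTimeS,
                  sensitivityScale = geometry@sensitivityScale,
                  strayReference = strayReference,
                  energyGroupKeV = geometry@energyGroupKeV))
}

#' Calibrate the sensitivity scale to a target count level
#'
#' Sets \code{sensitivityScale} so that the noise-free projection of the
#' given phantom totals \code{targetTotalCounts} across all windows
#' (default 2e5, the low-count regime of alpha-emitter SPECT, orders of
#' magnitude below conventional SPECT).
#'
#' @param phantom Reference \code{Phantom} (standard uptake).
#' @param geometry \code{ScannerGeometry} to calibrate.
#' @param windows,detector,spectra Forward-model components.
#' @param targetTotalCounts Desired total expected primary counts.
#' @return The geometry with calibrated \code{sensitivityScale}.
#' @export
calibrateSensitivity <- function(phantom, geometry = scannerGeometry(),
                                 windows = defaultEnergyWindows(),
                                 detector = detectorEnergyModel(),
                                 spectra = defaultSpectra(),
                                 targetTotalCounts = 2e5) {
  g1 <- geometry
  g1@sensitivityScale <- 1
  tot <- sum(projectPhantom(phantom, spectra, g1, windows, detector))
  if (tot <= 0) stop("phantom projects to zero counts; cannot calibrate")
  geometry@sensitivityScale <- targetTotalCounts / tot
  geometry
}

#' Simulate Poisson projection data on the VOI basis
#'
#' Counts are independently Poisson with mean \code{H lambda + psi}
#' (matched-model simulation: the same system matrices drive simulation and
#' estimation).
#'
#' @param sysmat \code{SystemMatrixSet}.
#' @param uptake \code{RegionalUptake} (truth).
#' @param seed Integer seed; realizations are reproducible.
#' @return A \code{\link{ProjectionData-class}}.
#' @export
simulateProjections <- function(sysmat, uptake, seed) {
  lam <- uptakeVector(uptake)
  if (length(lam) != ncol(sysmat@HTh) + ncol(sysmat@HRa))
    stop("uptake length does not match the system matrix")
  mu <- as.numeric(sysmat@HTh %*% uptake@lambdaTh +
                   sysmat@HRa %*% uptake@lambdaRa) + sysmat@psi
  stopifnot(all(mu >= 0))
  set.seed(seed)
  new("ProjectionData", counts = as.numeric(rpois(length(mu), mu)),
      projDim = sysmat@projDim, seed = as.integer(seed),
      meta = list(mode = "voi"))
}

#' Simulate Poisson projection data from the voxel maps
#'
#' Voxel-mode simulation for studies where the truth is not in the VOI basis
#' (lumpy heterogeneity, misregistration): the Poisson mean is the voxel
#' forward projection of the phantom plus the stray means.
#'
#' @param phantom \code{Phantom} (possibly heterogeneous or misregistered).
#' @param geometry,windows,detector,spectra Forward-model components.
#' @param strayReference,strayReferenceWindow,strayReferenceTimeS Stray-noise
#'   anchor (must match the system matrix used for estimation).
#' @param seed Integer seed.
#' @return A \code{\link{ProjectionData-class}}.
#' @export
simulateProjectionsVoxel <- function(phantom, geometry = scannerGeometry(),
                                     windows = defaultEnergyWindows(),
                                     detector = detectorEnergyModel(),
                                     spectra = defaultSpectra(),
                                     strayReference = 0.05,
                                     strayReferenceWindow = 3L,
                                     strayReferenceTimeS = 600,
                                     seed = 1L) {
  mu <- projectPhantom(phantom, spectra, geometry, windows, detector)
  n <- dim(phantom@voiLabels)
  nW <- length(windows@low)
  projDim <- as.integer(c(n[2], n[3], geometry@nAngles, nW))
  mu <- mu + strayNoiseMeans(windows, prod(projDim[1:3]),
                             geometry@acquisitionTimeS, strayReference,
                             strayReferenceWindow, strayReferenceTimeS)
  stopifnot(all(mu >= 0))
  set.seed(seed)
  new("ProjectionData", counts = as.numeric(rpois(length(mu), mu)),
      projDim = projDim, seed = as.integer(seed),
      meta = list(mode = "voxel"))
}
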