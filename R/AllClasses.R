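#' @import methods
#' @importFrom stats rpois rnorm runif approx pnorm sd rlnorm setNames
#' @importFrom utils read.delim modifyList
#' @importFrom tools md5sum
#' @importFrom Rcpp evalCpp
#' @useDynLib mewpdq, .registration = TRUE
NULL

#' Photon emission line spectrum of an isotope
#'
#' Holds the discrete X- and gamma-ray emission lines (energy in keV,
#' intensity in photons per decay) of either Thorium-227 or the Radium-223
#' decay chain (Ra-223 plus its short-lived daughters).  Lines are kept
#' sorted in ascending energy.
#'
#' @slot isotope Identifier, one of \code{"Th227"} or \code{"Ra223chain"}.
#' @slot energies Numeric vector of line energies (keV), strictly increasing.
#' @slot intensities Numeric vector of per-decay emission intensities.
#' @slot provenance Free-text citation of the nuclear-data source.
#' @exportClass LineSpectrum
setClass("LineSpectrum",
  representation(isotope = "character", energies = "numeric",
                 intensities = "numeric", provenance = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@energies) != length(object@intensities))
      msg <- c(msg, "energies and intensities must have equal length")
    if (any(object@energies <= 0)) msg <- c(msg, "energies must be positive")
    if (length(object@energies) > 1 && any(diff(object@energies) <= 0))
      msg <- c(msg, "energies must be strictly increasing")
    if (any(object@intensities < 0) || any(object@intensities > 10))
      msg <- c(msg, "intensities must lie in [0, 10]")
    if (length(msg)) msg else TRUE
  })

#' Acquisition energy windows
#'
#' A sorted, non-overlapping set of half-open energy windows
#' \code{[low, high)} in keV within which detected events are binned.
#'
#' @slot low,high Numeric vectors of window bounds (keV).
#' @exportClass EnergyWindows
setClass("EnergyWindows",
  representation(low = "numeric", high = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@low) != length(object@high))
      msg <- c(msg, "low and high must have equal length")
    if (any(object@low >= object@high))
      msg <- c(msg, "each window must satisfy low < high")
    n <- length(object@low)
    if (n > 1) {
      if (any(diff(object@low) <= 0)) msg <- c(msg, "windows must be sorted")
      if (any(object@high[-n] > object@low[-1]))
        msg <- c(msg, "windows must not overlap")
    }
    if (length(msg)) msg else TRUE
  })

#' Detector energy-response model
#'
#' Gaussian energy response with relative FWHM proportional to
#' \code{1/sqrt(E)}, anchored at a reference fraction and energy
#' (defaults: 9.8\% at 140 keV, NaI(Tl) behaviour).
#'
#' @slot fwhmFraction FWHM as a fraction of energy at the reference energy.
#' @slot refEnergy Reference energy in keV.
#' @exportClass DetectorEnergyModel
setClass("DetectorEnergyModel",
  representation(fwhmFraction = "numeric", refEnergy = "numeric"),
  validity = function(object) {
    if (object@fwhmFraction <= 0) return("fwhmFraction must be positive")
    if (object@refEnergy <= 0) return("refEnergy must be positive")
    TRUE
  })

#' Scanner geometry and acquisition settings
#'
#' Parallel-beam geometry of a rotating dual-head gamma camera.  Projection
#' bins are congruent with the phantom grid: \code{nu = ny}, \code{nv = nz}
#' detector bins of the voxel side length per view.
#'
#' @slot nAngles Number of angular positions spaced uniformly over 360 degrees.
#' @slot acquisitionTimeS Total acquisition time in seconds.
#' @slot intrinsicFwhmMm Intrinsic spatial resolution (mm FWHM).
#' @slot collimatorSlopeMmPerCm Collimator resolution slope (mm FWHM per cm
#'   source-to-collimator distance); high-energy general-purpose-like default.
#' @slot radiusMm Radius of rotation (mm, axis to collimator face).
#' @slot sensitivityScale Calibration constant converting emitted photons per
#'   view into detected counts (dimensionless detection efficiency).
#' @slot scatterFraction Scatter-to-primary fraction per energy window
#'   (recycled); the scatter surrogate adds this fraction of a broad-Gaussian
#'   blurred copy of the primary projection.
#' @slot scatterFwhmMm FWHM (mm) of the scatter surrogate blur.
#' @slot nDepthBands Number of depth bands sharing one collimator-blur kernel.
#' @slot energyGroupKeV Width (keV) of the energy groups into which emission
#'   lines are pooled for attenuation scaling (0 disables pooling).
#' @exportClass ScannerGeometry
setClass("ScannerGeometry",
  representation(nAngles = "integer", acquisitionTimeS = "numeric",
                 intrinsicFwhmMm = "numeric", collimatorSlopeMmPerCm = "numeric",
                 radiusMm = "numeric", sensitivityScale = "numeric",
                 scatterFraction = "numeric", scatterFwhmMm = "numeric",
                 nDepthBands = "integer", energyGroupKeV = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@nAngles < 1L) msg <- c(msg, "nAngles must be >= 1")
    if (object@acquisitionTimeS <= 0) msg <- c(msg, "acquisitionTimeS must be positive")
    if (object@intrinsicFwhmMm < 0 || object@collimatorSlopeMmPerCm < 0)
      msg <- c(msg, "resolutions must be non-negative")
    if (object@radiusMm <= 0) msg <- c(msg, "radiusMm must be positive")
    if (object@sensitivityScale <= 0) msg <- c(msg, "sensitivityScale must be positive")
    if (any(object@scatterFraction < 0)) msg <- c(msg, "scatterFraction must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Regional uptake of the two isotopes
#'
#' Mean activity concentration (Bq/mL) of Th-227 and Ra-223 in each volume
#' of interest.
#'
#' @slot lambdaTh,lambdaRa Named non-negative numeric vectors (Bq/mL), one
#'   entry per VOI.
#' @exportClass RegionalUptake
setClass("RegionalUptake",
  representation(lambdaTh = "numeric", lambdaRa = "numeric"),
  validity = function(object) {
    if (length(object@lambdaTh) != length(object@lambdaRa))
      return("lambdaTh and lambdaRa must have equal length")
    if (any(object@lambdaTh < 0) || any(object@lambdaRa < 0))
      return("uptake values must be non-negative")
    TRUE
  })

#' Digital phantom
#'
#' Voxelized torso phantom on an isotropic grid: integer VOI label map
#' (0 = outside the body), attenuation decomposed into soft-tissue-like and
#' bone-like components at the reference energy (140 keV, 1/cm), and one
#' activity concentration map (Bq/mL) per isotope.
#'
#' @slot voxelMm Isotropic voxel side length (mm).
#' @slot voiLabels Integer 3D array; 0 outside the body, k = 1..K inside VOI k.
#' @slot voiNames Character vector naming the K VOIs.
#' @slot muSoft,muBone Numeric 3D arrays: attenuation (1/cm at 140 keV)
#'   attributed to soft tissue and to bone; total attenuation is their sum.
#' @slot activityTh,activityRa Numeric 3D arrays of activity concentration
#'   (Bq/mL).
#' @slot uptake \code{RegionalUptake} used to fill the maps (ground truth).
#' @exportClass Phantom
setClass("Phantom",
  representation(voxelMm = "numeric", voiLabels = "array", voiNames = "character",
                 muSoft = "array", muBone = "array",
                 activityTh = "array", activityRa = "array",
                 uptake = "RegionalUptake"),
  validity = function(object) {
    d <- dim(object@voiLabels)
    msg <- character()
    for (s in c("muSoft", "muBone", "activityTh", "activityRa"))
      if (!identical(dim(slot(object, s)), d))
        msg <- c(msg, sprintf("%s must share the grid of voiLabels", s))
    if (object@voxelMm <= 0) msg <- c(msg, "voxelMm must be positive")
    if (any(object@activityTh < 0) || any(object@activityRa < 0))
      msg <- c(msg, "activity must be non-negative")
    if (any(object@muSoft < 0) || any(object@muBone < 0))
      msg <- c(msg, "attenuation must be non-negative")
    act <- object@activityTh + object@activityRa
    if (any(act > 0 & object@voiLabels == 0L))
      msg <- c(msg, "every voxel with activity > 0 must carry a VOI label")
    if (length(msg)) msg else TRUE
  })

#' Regional system matrices and stray-noise means
#'
#' The per-isotope M x K system matrices mapping regional uptake (Bq/mL) to
#' expected window-binned projection counts, together with the M-vector of
#' stray-radiation noise means (constant within each energy-window block).
#' Rows are ordered u-fastest, then v, then angle, then energy window
#' (window-major blocks).
#'
#' @slot HTh,HRa Non-negative M x K matrices (counts per Bq/mL).
#' @slot psi Numeric M-vector of stray-noise means (counts).
#' @slot projDim Integer vector (nu, nv, nAngles, nWindows).
#' @slot voiNames Character vector of VOI names (columns).
#' @slot windows The \code{EnergyWindows} used.
#' @slot meta List of build metadata (geometry, hashes, calibration).
#' @exportClass SystemMatrixSet
setClass("SystemMatrixSet",
  representation(HTh = "matrix", HRa = "matrix", psi = "numeric",
                 projDim = "integer", voiNames = "character",
                 windows = "EnergyWindows", meta = "list"),
  validity = function(object) {
    msg <- character()
    M <- prod(object@projDim)
    if (nrow(object@HTh) != M || nrow(object@HRa) != M)
      msg <- c(msg, "system matrix rows must equal prod(projDim)")
    if (ncol(object@HTh) != ncol(object@HRa))
      msg <- c(msg, "HTh and HRa must have the same number of columns")
    if (length(object@psi) != M) msg <- c(msg, "psi must have length M")
    if (any(object@HTh < 0) || any(object@HRa < 0) || any(object@psi < 0))
      msg <- c(msg, "system matrix and psi entries must be non-negative")
    Ms <- prod(object@projDim[1:3])
    psiw <- matrix(object@psi, nrow = Ms)
    if (ncol(psiw) > 0 &&
        any(abs(sweep(psiw, 2, psiw[1, ], "-")) > 1e-12 * (1 + max(object@psi))))
      msg <- c(msg, "psi must be constant within each energy-window block")
    if (length(msg)) msg else TRUE
  })

#' Measured or simulated projection data
#'
#' Integer-valued counts over all spatial bins and energy windows, in the
#' same window-major row order as \code{SystemMatrixSet}.
#'
#' @slot counts Numeric M-vector of non-negative integer counts.
#' @slot projDim Integer vector (nu, nv, nAngles, nWindows).
#' @slot seed Integer seed of the noise realization (NA when not simulated).
#' @slot meta Acquisition metadata list.
#' @exportClass ProjectionData
setClass("ProjectionData",
  representation(counts = "numeric", projDim = "integer", seed = "integer",
                 meta = "list"),
  validity = function(object) {
    if (length(object@counts) != prod(object@projDim))
      return("counts must have length prod(projDim)")
    if (any(object@counts < 0)) return("counts must be non-negative")
    if (any(object@counts != round(object@counts)))
      return("counts must be integer-valued")
    TRUE
  })

#' Joint uptake estimate
#'
#' Result of the joint EM estimator: the 2K-vector of regional uptake
#' estimates (Th block, then Ra block), the per-iteration log-likelihood
#' trace, thinned iterate snapshots and convergence diagnostics.
#'
#' @slot lambdaTh,lambdaRa Named numeric K-vectors (Bq/mL).
#' @slot logLik Numeric vector of log-likelihood values (one per recorded
#'   iteration, see \code{logLikIters}).
#' @slot logLikIters Iteration numbers at which \code{logLik} was recorded.
#' @slot trace Matrix of estimate snapshots (rows = recorded iterations,
#'   columns = 2K parameters).
#' @slot traceIters Iteration numbers of the snapshot rows.
#' @slot nIter Number of EM iterations performed.
#' @slot converged Logical: early-stopping tolerance reached.
#' @slot convergenceMetric Final maximal relative per-iteration change.
#' @exportClass UptakeEstimate
setClass("UptakeEstimate",
  representation(lambdaTh = "numeric", lambdaRa = "numeric",
                 logLik = "numeric", logLikIters = "numeric",
                 trace = "matrix", traceIters = "numeric",
                 nIter = "integer", converged = "logical",
                 convergenceMetric = "numeric"),
  validity = function(object) {
    if (any(object@lambdaTh < 0) || any(object@lambdaRa < 0))
      return("estimates must be non-negative")
    TRUE
  })

#' Fisher information for the composite uptake parameter
#'
#' Poisson Fisher information matrix over the composite (Th, Ra) parameter
#' vector, restricted to the projection rows of a chosen energy-window
#' subset.
#'
#' @slot matrix Symmetric non-negative-definite 2K x 2K matrix.
#' @slot lambda Evaluation point (2K-vector).
#' @slot windowSubset Integer vector of window indices used.
#' @exportClass FisherInfo
setClass("FisherInfo",
  representation(matrix = "matrix", lambda = "numeric",
                 windowSubset = "integer"),
  validity = function(object) {
    Fm <- object@matrix
    if (nrow(Fm) != ncol(Fm)) return("matrix must be square")
    if (max(abs(Fm - t(Fm))) > 1e-12 * (1 + max(abs(Fm))))
      return("matrix must be symmetric")
    TRUE
  })

#' Voxel-basis reconstruction
#'
#' Per-isotope voxel activity maps produced by the dual-isotope OSEM
#' baseline, with the protocol metadata.
#'
#' @slot mapTh,mapRa Non-negative numeric 3D arrays (Bq/mL).
#' @slot voxelMm Voxel side length (mm).
#' @slot nIters,nSubsets OSEM protocol used.
#' @exportClass VoxelRecon
setClass("VoxelRecon",
  representation(mapTh = "array", mapRa = "array", voxelMm = "numeric",
                 nIters = "integer", nSubsets = "integer"),
  validity = function(object) {
    if (!identical(dim(object@mapTh), dim(object@mapRa)))
      return("maps must share a grid")
    if (any(object@mapTh < 0) || any(object@mapRa < 0))
      return("voxel values must be non-negative")
    TRUE
  })
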