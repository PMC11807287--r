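#' Accessors for mewpdq classes
#'
#' Small accessor generics so that user code never touches slots directly.
#'
#' @param object A mewpdq S4 object.
#' @param ... Method arguments (e.g. \code{isotope}).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voiLabels", function(object) standardGeneric("voiLabels"))

#' @rdname accessors
#' @export
setGeneric("voiNames", function(object) standardGeneric("voiNames"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("muMap", function(object) standardGeneric("muMap"))

#' @rdname accessors
#' @export
setGeneric("activityMap", function(object, isotope) standardGeneric("activityMap"))

#' @rdname accessors
#' @export
setGeneric("regionalUptake", function(object) standardGeneric("regionalUptake"))

#' @rdname accessors
#' @export
setGeneric("uptakeVector", function(object) standardGeneric("uptakeVector"))

#' @rdname accessors
#' @export
setGeneric("systemMatrix", function(object, isotope) standardGeneric("systemMatrix"))

#' @rdname accessors
#' @export
setGeneric("strayMeans", function(object) standardGeneric("strayMeans"))

#' @rdname accessors
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("logLikTrace", function(object) standardGeneric("logLikTrace"))

#' @rdname accessors
#' @export
setGeneric("estimateTrace", function(object) standardGeneric("estimateTrace"))

#' @rdname accessors
#' @export
setGeneric("nWindows", function(object) standardGeneric("nWindows"))

setMethod("voiLabels", "Phantom", function(object) object@voiLabels)
setMethod("voiNames", "Phantom", function(object) object@voiNames)
setMethod("voiNames", "SystemMatrixSet", function(object) object@voiNames)
setMethod("voxelSize", "Phantom", function(object) object@voxelMm)
setMethod("voxelSize", "VoxelRecon", function(object) object@voxelMm)
setMethod("muMap", "Phantom", function(object) object@muSoft + object@muBone)

setMethod("activityMap", "Phantom", function(object, isotope) {
  switch(match.arg(isotope, c("Th", "Ra")),
         Th = object@activityTh, Ra = object@activityRa)
})
setMethod("activityMap", "VoxelRecon", function(object, isotope) {
  switch(match.arg(isotope, c("Th", "Ra")),
         Th = object@mapTh, Ra = object@mapRa)
})

setMethod("regionalUptake", "Phantom", function(object) object@uptake)
setMethod("regionalUptake", "UptakeEstimate", function(object)
  new("RegionalUptake", lambdaTh = object@lambdaTh, lambdaRa = object@lambdaRa))

#' @describeIn accessors Composite 2K-vector (Th block then Ra block).
setMethod("uptakeVector", "RegionalUptake", function(object)
  c(object@lambdaTh, object@lambdaRa))
setMethod("uptakeVector", "UptakeEstimate", function(object)
  c(object@lambdaTh, object@lambdaRa))

setMethod("systemMatrix", "SystemMatrixSet", function(object, isotope) {
  switch(match.arg(isotope, c("Th", "Ra", "composite")),
         Th = object@HTh, Ra = object@HRa,
         composite = cbind(object@HTh, object@HRa))
})
setMethod("strayMeans", "SystemMatrixSet", function(object) object@psi)
setMethod("counts", "ProjectionData", function(object) object@counts)
setMethod("logLikTrace", "UptakeEstimate", function(object)
  data.frame(iteration = object@logLikIters, logLik = object@logLik))
setMethod("estimateTrace", "UptakeEstimate", function(object) {
  tr <- object@trace
  attr(tr, "iterations") <- object@traceIters
  tr
})
setMethod("nWindows", "EnergyWindows", function(object) length(object@low))
setMethod("nWindows", "SystemMatrixSet", function(object) object@projDim[4L])

#' Number of VOIs
#' @param object A \code{Phantom}, \code{SystemMatrixSet} or \code{RegionalUptake}.
#' @export
setGeneric("nRegions", function(object) standardGeneric("nRegions"))
setMethod("nRegions", "Phantom", function(object) length(object@voiNames))
setMethod("nRegions", "SystemMatrixSet", function(object) ncol(object@HTh))
setMethod("nRegions", "RegionalUptake", function(object) length(object@lambdaTh))

setMethod("show", "LineSpectrum", function(object) {
  cat(sprintf("LineSpectrum: %s, %d lines, %.1f-%.1f keV, total %.3f photons/decay\n",
              object@isotope, length(object@energies),
              min(object@energies), max(object@energies),
              sum(object@intensities)))
  cat(" provenance:", object@provenance, "\n")
})

setMethod("show", "EnergyWindows", function(object) {
  cat(sprintf("EnergyWindows: %d half-open windows [low, high) keV\n",
              length(object@low)))
  for (i in seq_along(object@low))
    cat(sprintf("  W%d: [%g, %g)\n", i, object@low[i], object@high[i]))
})

setMethod("show", "Phantom", function(object) {
  d <- dim(object@voiLabels)
  cat(sprintf("Phantom: %dx%dx%d voxels @ %.3f mm\n", d[1], d[2], d[3],
              object@voxelMm))
  vv <- (object@voxelMm / 10)^3
  cat(sprintf(" VOIs: %s\n", paste(object@voiNames, collapse = ", ")))
  cat(sprintf(" total activity: Th %.3g MBq, Ra %.3g MBq\n",
              sum(object@activityTh) * vv / 1e6,
              sum(object@activityRa) * vv / 1e6))
})

setMethod("show", "SystemMatrixSet", function(object) {
  pd <- object@projDim
  cat(sprintf("SystemMatrixSet: M = %d (%dx%d bins x %d angles x %d windows), K = %d\n",
              prod(pd), pd[1], pd[2], pd[3], pd[4], ncol(object@HTh)))
  cat(sprintf(" column sums (Th): %s\n",
              paste(signif(colSums(object@HTh), 3), collapse = " ")))
  cat(sprintf(" column sums (Ra): %s\n",
              paste(signif(colSums(object@HRa), 3), collapse = " ")))
})

setMethod("show", "ProjectionData", function(object) {
  pd <- object@projDim
  cat(sprintf("ProjectionData: %d bins (%dx%dx%d angles x %d windows), %d total counts\n",
              prod(pd), pd[1], pd[2], pd[3], pd[4], sum(object@counts)))
})

setMethod("show", "UptakeEstimate", function(object) {
  cat(sprintf("UptakeEstimate after %d iterations (converged: %s)\n",
              object@nIter, object@converged))
  est <- rbind(Th = object@lambdaTh, Ra = object@lambdaRa)
  print(signif(est, 4))
})

setMethod("show", "RegionalUptake", function(object) {
  cat("RegionalUptake (Bq/mL):\n")
  print(signif(rbind(Th = object@lambdaTh, Ra = object@lambdaRa), 4))
})

setMethod("show", "FisherInfo", function(object) {
  cat(sprintf("FisherInfo: %dx%d, windows {%s}\n", nrow(object@matrix),
              ncol(object@matrix), paste(object@windowSubset, collapse = ",")))
})

setMethod("show", "VoxelRecon", function(object) {
  d <- dim(object@mapTh)
  cat(sprintf("VoxelRecon: %dx%dx%d @ %.3f mm, %d iterations x %d subsets\n",
              d[1], d[2], d[3], object@voxelMm, object@nIters, object@nSubsets))
})

#' Construct a RegionalUptake object
#'
#' @param lambdaTh,lambdaRa Non-negative numeric vectors of mean regional
#'   activity concentration (Bq/mL), one entry per VOI.
#' @param names Optional VOI names.
#' @return A \code{RegionalUptake}.
#' @export
regionalUptakeValues <- function(lambdaTh, lambdaRa, names = NULL) {
  if (!is.null(names)) {
    names(lambdaTh) <- names
    names(lambdaRa) <- names
  }
  new("RegionalUptake", lambdaTh = lambdaTh, lambdaRa = lambdaRa)
}
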