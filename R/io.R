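# Serialization: phantoms as NIfTI volumes with a JSON sidecar manifest;
# system matrices and projections in an RDS container with a JSON metadata
# export; uptake estimates as structured JSON.

#' Write a phantom as NIfTI volumes
#'
#' One file per map (\code{voi.nii.gz}, \code{mu.nii.gz},
#' \code{activityTh.nii.gz}, \code{activityRa.nii.gz}) plus a JSON sidecar
#' manifest (\code{manifest.json}) with the VOI names, voxel size and
#' ground-truth uptake.
#'
#' @param phantom A \code{Phantom}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
writePhantomNifti <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- phantom@voxelMm
  wr <- function(arr, name)
    RNifti::writeNifti(RNifti::asNifti(arr, pixdim = c(v, v, v)),
                       file.path(dir, paste0(name, ".nii.gz")))
  wr(phantom@voiLabels + 0, "voi")
  wr(muMap(phantom), "mu")
  wr(phantom@muBone, "muBone")
  wr(phantom@activityTh, "activityTh")
  wr(phantom@activityRa, "activityRa")
  manifest <- list(voxelMm = v, voiNames = phantom@voiNames,
                   lambdaTh = as.list(phantom@uptake@lambdaTh),
                   lambdaRa = as.list(phantom@uptake@lambdaRa),
                   generator = paste("mewpdq", as.character(utils::packageVersion("mewpdq"))))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a phantom written by \code{\link{writePhantomNifti}}
#'
#' @param dir Directory containing the NIfTI volumes and manifest.
#' @return A \code{Phantom}.
#' @export
readPhantomNifti <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  rd <- function(name) {
    a <- RNifti::readNifti(file.path(dir, paste0(name, ".nii.gz")))
    array(as.numeric(a), dim = dim(a))
  }
  mu <- rd("mu"); muBone <- rd("muBone")
  new("Phantom", voxelMm = manifest$voxelMm,
      voiLabels = array(as.integer(round(rd("voi"))), dim = dim(mu)),
      voiNames = manifest$voiNames,
      muSoft = pmax(mu - muBone, 0), muBone = muBone,
      activityTh = rd("activityTh"), activityRa = rd("activityRa"),
      uptake = regionalUptakeValues(unlist(manifest$lambdaTh),
                                    unlist(manifest$lambdaRa),
                                    names = manifest$voiNames))
}

#' Save / load a system matrix container
#'
#' The container is an RDS file holding the validated object; alongside it a
#' JSON metadata file (same path with extension \code{.json}) records the
#' layout (projection dimensions, window bounds, VOI names, build metadata)
#' so the container is self-describing.
#'
#' @param sysmat A \code{SystemMatrixSet}.
#' @param path Output path (conventionally \code{.rds}).
#' @return Invisibly, \code{path}.
#' @export
saveSystemMatrix <- function(sysmat, path) {
  validObject(sysmat)
  saveRDS(sysmat, path)
  meta <- list(projDim = sysmat@projDim, voiNames = sysmat@voiNames,
               windows = list(low = sysmat@windows@low,
                              high = sysmat@windows@high),
               meta = sysmat@meta)
  jsonlite::write_json(meta, paste0(sub("\\.rds$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveSystemMatrix
#' @export
readSystemMatrix <- function(path) {
  obj <- readRDS(path)
  validObject(obj)
  obj
}

#' Write an uptake estimate as structured JSON
#'
#' Full provenance: estimates per isotope and VOI, iteration count,
#' convergence diagnostics and the log-likelihood trace.
#'
#' @param estimate An \code{UptakeEstimate}.
#' @param path Output JSON path.
#' @param extra Optional named list merged into the output (seeds, hashes).
#' @return Invisibly, \code{path}.
#' @export
writeUptakeEstimate <- function(estimate, path, extra = list()) {
  out <- c(list(lambdaTh = as.list(estimate@lambdaTh),
                lambdaRa = as.list(estimate@lambdaRa),
                nIter = estimate@nIter,
                converged = estimate@converged,
                convergenceMetric = estimate@convergenceMetric,
                logLik = estimate@logLik,
                logLikIters = estimate@logLikIters),
           extra)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
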