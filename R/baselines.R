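# Conventional reconstruction-based quantification baselines: dual-isotope
# OSEM voxel reconstruction (DOSEM) with VOI averaging, and geometric
# transfer matrix (GTM) partial-volume compensation.
#
# The voxel forward model is the same simplified projector used elsewhere,
# applied matrix-free per subset (an explicit voxel system matrix would be
# prohibitively large).  Several independent reconstruction problems can be
# run as one batch sharing the per-angle rotation/attenuation work; the GTM
# build exploits this for its K unit-VOI reconstructions.

`%||%` <- function(a, b) if (is.null(a)) b else a

.asUptakeVector <- function(x) {
  if (is(x, "UptakeEstimate") || is(x, "RegionalUptake")) return(uptakeVector(x))
  if (is.list(x) && !is.null(x$lambdaTh)) return(c(x$lambdaTh, x$lambdaRa))
  stop("cannot interpret object as an uptake vector")
}

.proj4d <- function(g, projDim) {
  if (is(g, "ProjectionData")) g <- counts(g)
  array(g, dim = projDim)
}

# batched joint OSEM over a list of projection data sets
.dosemBatch <- function(gList, phantom, geometry, windows, detector, spectra,
                        nIters, nSubsets, strayReference = 0.05,
                        strayReferenceWindow = 3L, strayReferenceTimeS = 600,
                        trackLogLik = FALSE) {
  nA <- geometry@nAngles
  if (nA %% nSubsets != 0)
    stop("nAngles (", nA, ") is not divisible by nSubsets (", nSubsets, ")")
  n <- dim(phantom@voiLabels)
  nW <- length(windows@low)
  projDim <- c(n[2], n[3], nA, nW)
  B <- length(gList)
  g4 <- lapply(gList, .proj4d, projDim = projDim)
  for (g in g4) if (any(g < 0)) stop("negative counts")

  argsTh <- .projArgs(phantom, geometry, windows, detector, spectra$Th)
  argsRa <- .projArgs(phantom, geometry, windows, detector, spectra$Ra)
  psiW <- strayNoiseMeans(windows, 1L, geometry@acquisitionTimeS,
                          strayReference, strayReferenceWindow,
                          strayReferenceTimeS)  # per-window scalar means

  subsetIdx <- lapply(seq_len(nSubsets), function(s) seq(s, nA, by = nSubsets))
  subArgs <- function(args, idx) { args$angles <- args$angles[idx]; args }
  npixA <- function(idx) c(n[2], n[3], length(idx), nW)

  onesProj <- function(idx) as.numeric(array(1, dim = npixA(idx)))
  sensTh <- lapply(subsetIdx, function(idx)
    .backward(onesProj(idx), subArgs(argsTh, idx))[[1]])
  sensRa <- lapply(subsetIdx, function(idx)
    .backward(onesProj(idx), subArgs(argsRa, idx))[[1]])
  totSens <- sum(Reduce(`+`, sensTh)) + sum(Reduce(`+`, sensRa))
  psiTot <- sum(psiW) * prod(projDim[1:3])

  fTh <- fRa <- vector("list", B)
  for (b in seq_len(B)) {
    f0 <- max(sum(g4[[b]]) - psiTot, 0) / max(totSens, 1e-300)
    fTh[[b]] <- array(f0, dim = n)
    fRa[[b]] <- array(f0, dim = n)
  }

  psiSub <- function(idx)
    array(rep(psiW, each = prod(c(n[2], n[3], length(idx)))), dim = npixA(idx))
  ll <- if (trackLogLik) matrix(NA_real_, nIters, B) else NULL
  allIdx <- seq_len(nA)
  for (it in seq_len(nIters)) {
    for (s in seq_len(nSubsets)) {
      idx <- subsetIdx[[s]]
      aTh <- subArgs(argsTh, idx); aRa <- subArgs(argsRa, idx)
      pTh <- .forward(fTh, aTh)   # (ny,nz,ns,nW,B) as a flat vector
      pRa <- .forward(fRa, aRa)
      nsub <- prod(npixA(idx))
      psiS <- as.numeric(psiSub(idx))
      ratios <- vector("list", B)
      for (b in seq_len(B)) {
        mu <- pTh[(b - 1) * nsub + seq_len(nsub)] +
              pRa[(b - 1) * nsub + seq_len(nsub)] + psiS
        gSub <- as.numeric(g4[[b]][, , idx, , drop = FALSE])
        r <- numeric(nsub)
        ok <- mu >= 1e-30
        r[ok] <- gSub[ok] / mu[ok]
        ratios[[b]] <- r
      }
      bTh <- .backward(ratios, aTh)
      bRa <- .backward(ratios, aRa)
      sT <- sensTh[[s]]; sR <- sensRa[[s]]
      posT <- sT > 0; posR <- sR > 0
      for (b in seq_len(B)) {
        newT <- array(0, dim = n); newR <- array(0, dim = n)
        newT[posT] <- fTh[[b]][posT] * bTh[[b]][posT] / sT[posT]
        newR[posR] <- fRa[[b]][posR] * bRa[[b]][posR] / sR[posR]
        fTh[[b]] <- newT; fRa[[b]] <- newR
      }
    }
    if (trackLogLik) {
      pTh <- .forward(fTh, argsTh); pRa <- .forward(fRa, argsRa)
      nfull <- prod(projDim)
      psiF <- as.numeric(psiSub(allIdx))
      for (b in seq_len(B)) {
        mu <- pTh[(b - 1) * nfull + seq_len(nfull)] +
              pRa[(b - 1) * nfull + seq_len(nfull)] + psiF
        ok <- mu > 0
        ll[it, b] <- sum(as.numeric(g4[[b]])[ok] * log(mu[ok])) - sum(mu)
      }
    }
  }
  recons <- vector("list", B)
  for (b in seq_len(B)) {
    recons[[b]] <- new("VoxelRecon", mapTh = fTh[[b]], mapRa = fRa[[b]],
                       voxelMm = phantom@voxelMm, nIters = as.integer(nIters),
                       nSubsets = as.integer(nSubsets))
    if (trackLogLik) attr(recons[[b]], "logLik") <- ll[, b]
  }
  recons
}

#' Dual-isotope OSEM reconstruction
#'
#' Joint ordered-subset EM over the voxel basis: both isotopes' maps are
#' updated per subset with the shared composite denominator (the voxel
#' analogue of the regional EM update, stray means included).  With one
#' subset this is dual-isotope MLEM.  Counts may be non-integer (e.g.
#' noiseless expected data when building a GTM).
#'
#' @param g \code{ProjectionData} or counts vector/array.
#' @param phantom \code{Phantom} supplying grid and attenuation.
#' @param geometry,windows,detector,spectra Forward-model components.
#' @param nIters Number of full iterations.
#' @param nSubsets Number of angular subsets; must divide \code{nAngles}.
#' @param strayReference,strayReferenceWindow,strayReferenceTimeS Stray-noise
#'   anchor (matched to the simulation).
#' @param trackLogLik If TRUE, compute the full-data log-likelihood after
#'   every full iteration (costly; attached as attribute \code{logLik}).
#' @return A \code{\link{VoxelRecon-class}}.
#' @export
dosemReconstruct <- function(g, phantom, geometry = scannerGeometry(),
                             windows = defaultEnergyWindows(),
                             detector = detectorEnergyModel(),
                             spectra = defaultSpectra(),
                             nIters = 40L, nSubsets = 15L,
                             strayReference = 0.05,
                             strayReferenceWindow = 3L,
                             strayReferenceTimeS = 600,
                             trackLogLik = FALSE) {
  .dosemBatch(list(g), phantom, geometry, windows, detector, spectra,
              nIters, nSubsets, strayReference, strayReferenceWindow,
              strayReferenceTimeS, trackLogLik)[[1]]
}

#' Mean reconstructed uptake per VOI
#'
#' @param recon \code{VoxelRecon}.
#' @param voiLabels Integer label array aligned with the reconstruction grid
#'   (or a \code{Phantom} whose labels are used).
#' @return A \code{RegionalUptake} of per-region voxel means.
#' @export
voiMeanUptake <- function(recon, voiLabels) {
  if (is(voiLabels, "Phantom")) {
    nm <- voiLabels@voiNames
    voiLabels <- voiLabels@voiLabels
  } else nm <- NULL
  if (!identical(dim(voiLabels), dim(recon@mapTh)))
    stop("label map does not share the reconstruction grid")
  K <- max(voiLabels)
  lamTh <- lamRa <- numeric(K)
  for (k in seq_len(K)) {
    sel <- voiLabels == k
    if (!any(sel)) stop("VOI ", k, " is empty")
    lamTh[k] <- mean(recon@mapTh[sel])
    lamRa[k] <- mean(recon@mapRa[sel])
  }
  regionalUptakeValues(pmax(lamTh, 0), pmax(lamRa, 0), names = nm)
}

#' Build the geometric transfer matrices
#'
#' Rousset-style regional spread functions through the matched pipeline: for
#' each isotope and VOI, the noiseless expected projection of that VOI at a
#' reference uptake (plus stray means) is reconstructed with the same DOSEM
#' protocol used for the data, and entry (k, l) of the K x K matrix is the
#' mean of the reconstruction over VOI k per unit uptake in VOI l.  The K
#' reconstructions are run as one batch.
#'
#' @param sysmat \code{SystemMatrixSet} of the patient (its columns are the
#'   unit-VOI projections).
#' @param phantom The patient \code{Phantom}.
#' @param geometry,windows,detector,spectra Forward-model components.
#' @param nIters,nSubsets DOSEM protocol (match the data reconstruction).
#' @param refUptake Optional \code{RegionalUptake} setting the count scale of
#'   each unit-VOI reconstruction (defaults to the phantom's stored uptake so
#'   the count regime matches the acquisition).
#' @return List with K x K matrices \code{Th} and \code{Ra}; lack of
#'   diagonal dominance is reported as a warning, not an error.
#' @export
gtmMatrix <- function(sysmat, phantom, geometry = scannerGeometry(),
                      windows = defaultEnergyWindows(),
                      detector = detectorEnergyModel(),
                      spectra = defaultSpectra(),
                      nIters = 40L, nSubsets = 15L, refUptake = NULL) {
  K <- nRegions(sysmat)
  if (is.null(refUptake)) refUptake <- phantom@uptake
  out <- list()
  for (iso in c("Th", "Ra")) {
    H <- systemMatrix(sysmat, iso)
    lamRef <- if (iso == "Th") refUptake@lambdaTh else refUptake@lambdaRa
    lamRef <- pmax(lamRef, 1e-6 * max(lamRef))
    gList <- lapply(seq_len(K), function(l) H[, l] * lamRef[l] + sysmat@psi)
    recons <- .dosemBatch(gList, phantom, geometry, windows, detector,
                          spectra, nIters = nIters, nSubsets = nSubsets,
                          strayReference = sysmat@meta$strayReference %||% 0.05)
    Om <- matrix(0, K, K, dimnames = list(sysmat@voiNames, sysmat@voiNames))
    for (l in seq_len(K)) {
      mk <- voiMeanUptake(recons[[l]], phantom@voiLabels)
      resp <- if (iso == "Th") mk@lambdaTh else mk@lambdaRa
      Om[, l] <- resp / lamRef[l]
    }
    if (any(diag(Om) < rowSums(Om) - diag(Om)))
      warning("GTM matrix for ", iso, " is not diagonally dominant")
    out[[iso]] <- Om
  }
  out
}

#' Run both reconstruction-based baselines on one data set
#'
#' Reconstructs the measured projections with DOSEM and, in the same batch,
#' the noiseless unit-VOI projections needed for the GTM matrices of both
#' isotopes (nine reconstruction problems sharing the per-angle geometry
#' work).  Returns the raw DOSEM VOI means and the GTM-corrected estimates.
#'
#' @param g \code{ProjectionData} (or counts) for the patient.
#' @param sysmat The patient's \code{SystemMatrixSet}.
#' @param phantom The patient \code{Phantom}.
#' @param geometry,windows,detector,spectra Forward-model components.
#' @param nIters,nSubsets DOSEM protocol.
#' @return List with \code{dosem} (\code{RegionalUptake}), \code{gtm}
#'   (list from \code{\link{gtmCorrect}}) and \code{omega}.
#' @export
baselineQuantify <- function(g, sysmat, phantom, geometry = scannerGeometry(),
                             windows = defaultEnergyWindows(),
                             detector = detectorEnergyModel(),
                             spectra = defaultSpectra(),
                             nIters = 40L, nSubsets = 15L) {
  K <- nRegions(sysmat)
  ref <- phantom@uptake
  gList <- list(if (is(g, "ProjectionData")) counts(g) else g)
  scales <- list()
  for (iso in c("Th", "Ra")) {
    H <- systemMatrix(sysmat, iso)
    lamRef <- if (iso == "Th") ref@lambdaTh else ref@lambdaRa
    lamRef <- pmax(lamRef, 1e-6 * max(lamRef))
    scales[[iso]] <- lamRef
    for (l in seq_len(K)) gList <- c(gList, list(H[, l] * lamRef[l] + sysmat@psi))
  }
  recons <- .dosemBatch(gList, phantom, geometry, windows, detector, spectra,
                        nIters = nIters, nSubsets = nSubsets,
                        strayReference = sysmat@meta$strayReference %||% 0.05)
  raw <- voiMeanUptake(recons[[1]], phantom@voiLabels)
  names(raw@lambdaTh) <- names(raw@lambdaRa) <- sysmat@voiNames
  omega <- list()
  at <- 1L
  for (iso in c("Th", "Ra")) {
    Om <- matrix(0, K, K, dimnames = list(sysmat@voiNames, sysmat@voiNames))
    for (l in seq_len(K)) {
      at <- at + 1L
      mk <- voiMeanUptake(recons[[at]], phantom@voiLabels)
      resp <- if (iso == "Th") mk@lambdaTh else mk@lambdaRa
      Om[, l] <- resp / scales[[iso]][l]
    }
    omega[[iso]] <- Om
  }
  list(dosem = raw, gtm = gtmCorrect(raw, omega), omega = omega)
}

#' Apply GTM partial-volume correction
#'
#' Corrected uptake \code{Omega^{-1} raw} per isotope.  Negative corrected
#' values can occur at low counts and are reported as-is (flagged in the
#' result).
#'
#' @param raw \code{RegionalUptake} of raw VOI means (from
#'   \code{\link{voiMeanUptake}}).
#' @param omega List with matrices \code{Th} and \code{Ra} from
#'   \code{\link{gtmMatrix}}.
#' @return List with \code{lambdaTh}, \code{lambdaRa} (possibly negative)
#'   and \code{negative} flag.
#' @export
gtmCorrect <- function(raw, omega) {
  solveOne <- function(Om, v) {
    d <- tryCatch(determinant(Om, logarithm = FALSE)$modulus,
                  error = function(e) 0)
    if (!is.finite(d) || d == 0) stop("singular GTM matrix")
    as.numeric(solve(Om, v))
  }
  lamTh <- solveOne(omega$Th, raw@lambdaTh)
  lamRa <- solveOne(omega$Ra, raw@lambdaRa)
  names(lamTh) <- names(raw@lambdaTh); names(lamRa) <- names(raw@lambdaRa)
  list(lambdaTh = lamTh, lambdaRa = lamRa,
       negative = any(c(lamTh, lamRa) < 0))
}
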