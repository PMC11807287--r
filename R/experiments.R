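# Desk-scale reproductions of the evaluation study designs: convergence,
# lesion size / contrast / isotope-ratio sweeps, energy-window CRLB study,
# virtual imaging trial, heterogeneity and misregistration robustness.
#
# Every experiment is a pure function of (config, seed): per-condition and
# per-realization seeds are derived from the master seed by a counter-based
# scheme, and all problem sizes are config switches.

#' Experiment configuration
#'
#' Bundles the phantom grid, scanner settings, count-level calibration and
#' realization counts for the experiment drivers.  Three profiles are
#' provided: \code{"desk"} (default; minutes per experiment on one CPU),
#' \code{"test"} (seconds; used by the unit tests) and \code{"paper"} (the
#' full-scale protocol: 128x128x96 grid at 2.21 mm, 60 views, 50
#' realizations, 60 patients, DOSEM 40x15).
#'
#' @param profile One of \code{"desk"}, \code{"test"}, \code{"paper"}.
#' @param ... Named overrides of any configuration field.
#' @return Configuration list.
#' @export
experimentConfig <- function(profile = c("desk", "test", "paper"), ...) {
  profile <- match.arg(profile)
  base <- switch(profile,
    desk = list(grid = phantomGrid(c(42L, 42L, 30L), 7.08), nAngles = 16L,
                nRealizations = 25L, nPatients = 60L, nHetPatients = 5L,
                dosemIters = 2L, dosemSubsets = 8L,
                energyGroupKeV = 20, nDepthBands = 5L),
    test = list(grid = phantomGrid(c(32L, 32L, 24L), 8.85), nAngles = 8L,
                nRealizations = 5L, nPatients = 4L, nHetPatients = 2L,
                dosemIters = 2L, dosemSubsets = 4L,
                energyGroupKeV = 20, nDepthBands = 4L),
    paper = list(grid = phantomGrid(c(128L, 128L, 96L), 2.21), nAngles = 60L,
                 nRealizations = 50L, nPatients = 60L, nHetPatients = 5L,
                 dosemIters = 40L, dosemSubsets = 15L,
                 energyGroupKeV = 10, nDepthBands = 8L))
  cfg <- c(base, list(
    profile = profile,
    acquisitionTimeS = 1800,
    targetTotalCounts = 2e5,
    strayReference = 0.05,
    emIters = 1000L,
    seed = 1L,
    lesionDiameterMm = 33.75,
    thRaRatio = 5,
    totalActivityBq = 11e6,
    hetW = c(0, 0.1, 0.2, 0.3, 0.4, 0.8, 1),
    shiftsX = c(2, 4, 6, 9), shiftsY = c(2, 4, 6), rotationsDeg = c(1, 2),
    methods = c("mewpdq", "dosem", "gtm")))
  modifyList(cfg, list(...))
}

# counter-based sub-seed derivation (kept below 2^31)
.deriveSeed <- function(master, stream, counter = 0L) {
  as.integer((as.double(master) * 7919 + stream * 104729 + counter * 257) %%
               2147483629) + 1L
}

.configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

# assemble the shared imaging setup: standard phantom, calibrated geometry
.studySetup <- function(config, lesionDiameterMm = config$lesionDiameterMm,
                        uptake = NULL, totalActivityBq = NULL) {
  windows <- defaultEnergyWindows()
  detector <- detectorEnergyModel()
  spectra <- defaultSpectra()
  if (is.null(totalActivityBq))
    totalActivityBq <- standardTotalActivity(config$totalActivityBq,
                                             config$thRaRatio)
  phantom <- makePelvicPhantom(grid = config$grid,
                               lesionDiameterMm = lesionDiameterMm,
                               uptake = uptake,
                               totalActivityBq = totalActivityBq)
  geometry <- scannerGeometry(nAngles = config$nAngles,
                              acquisitionTimeS = config$acquisitionTimeS,
                              energyGroupKeV = config$energyGroupKeV,
                              nDepthBands = config$nDepthBands)
  geometry <- calibrateSensitivity(phantom, geometry, windows, detector,
                                   spectra, config$targetTotalCounts)
  list(phantom = phantom, geometry = geometry, windows = windows,
       detector = detector, spectra = spectra)
}

.buildH <- function(phantom, setup, config)
  buildSystemMatrix(phantom, setup$geometry, setup$windows, setup$detector,
                    setup$spectra, strayReference = config$strayReference)

# run the configured quantification methods on one data set
.quantifyAll <- function(g, sysmat, phantom, setup, config) {
  out <- list()
  if ("mewpdq" %in% config$methods)
    out$mewpdq <- runMewPdq(g, sysmat, maxIter = config$emIters,
                            traceEvery = 0L, logLikEvery = 0L)
  if (any(c("dosem", "gtm") %in% config$methods)) {
    if ("gtm" %in% config$methods) {
      bl <- baselineQuantify(g, sysmat, phantom, setup$geometry,
                             setup$windows, setup$detector, setup$spectra,
                             nIters = config$dosemIters,
                             nSubsets = config$dosemSubsets)
      if ("dosem" %in% config$methods) out$dosem <- bl$dosem
      out$gtm <- bl$gtm
    } else {
      recon <- dosemReconstruct(g, phantom, setup$geometry, setup$windows,
                                setup$detector, setup$spectra,
                                nIters = config$dosemIters,
                                nSubsets = config$dosemSubsets,
                                strayReference = config$strayReference)
      out$dosem <- voiMeanUptake(recon, phantom)
    }
  }
  out
}

#' Convergence study of the projection-domain estimator
#'
#' One noise realization for each of three lesion diameters (15, 25, 35 mm)
#' at standard uptake; the estimator runs for 1500 iterations and the
#' normalized lesion-uptake error is recorded every 50 iterations.  The
#' stabilization iteration is the earliest recorded iteration from which the
#' lesion estimates of both isotopes stay within 0.5 percent of their
#' iteration-1500 value for all lesion sizes.
#'
#' @param config An \code{\link{experimentConfig}}.
#' @param diameters Lesion diameters (mm).
#' @return List with \code{errors} (data frame: diameter, isotope,
#'   iteration, normalized error), \code{stableIteration} and
#'   \code{manifest}.
#' @export
runConvergenceStudy <- function(config = experimentConfig(),
                                diameters = c(15, 25, 35)) {
  errTab <- NULL
  stableBy <- NULL
  setup <- .studySetup(config)  # sensitivity calibrated once, standard phantom
  for (d in diameters) {
    phantom <- makePelvicPhantom(
      grid = config$grid, lesionDiameterMm = d,
      totalActivityBq = standardTotalActivity(config$totalActivityBq,
                                              config$thRaRatio))
    sysmat <- .buildH(phantom, setup, config)
    truth <- regionalUptake(phantom)
    g <- simulateProjections(sysmat, truth,
                             seed = .deriveSeed(config$seed, 1L, round(d)))
    est <- runMewPdq(g, sysmat, maxIter = 1500L, traceEvery = 50L,
                     logLikEvery = 0L)
    tr <- estimateTrace(est)
    iters <- attr(tr, "iterations")
    K <- nRegions(sysmat)
    les <- which(sysmat@voiNames == "lesion")
    for (isoIdx in 1:2) {
      col <- (isoIdx - 1) * K + les
      tru <- uptakeVector(truth)[col]
      errTab <- rbind(errTab, data.frame(
        diameter = d, isotope = c("Th", "Ra")[isoIdx], iteration = iters,
        normError = (tr[, col] - tru) / tru))
      ref <- tr[length(iters), col]
      rel <- abs(tr[, col] - ref) / abs(ref)
      okFrom <- rev(cumprod(rev(rel < 0.005))) == 1
      stableBy <- c(stableBy, iters[which(okFrom)[1]])
    }
  }
  list(errors = errTab, stableIteration = max(stableBy),
       manifest = list(configHash = .configHash(config), seed = config$seed,
                       diameters = diameters))
}

#' Parameter sweeps: lesion diameter, lesion contrast, isotope ratio
#'
#' Repeated-realization evaluation across one swept dimension:
#' \code{"lesion_diameter"} (15 to 35 mm), \code{"lbur"} (lesion-to-bone
#' uptake ratio 2:1 to 6:1 for both isotopes at 33.75 mm) or
#' \code{"th_ra_ratio"} (global activity ratio 10:1, 5:1, 3:1, 1:1).
#' Non-swept uptake ratios stay at their standard values.  The CRLB-derived
#' NSD is computed alongside for comparison with the estimator's NSD.
#'
#' @param dimension Swept dimension.
#' @param config An \code{\link{experimentConfig}}.
#' @param values Optional sweep values (defaults follow the study design).
#' @return List with \code{merit} (per-condition merit data frame),
#'   \code{crlb} (per-condition CRLB-NSD) and \code{manifest}.
#' @export
runSweep <- function(dimension = c("lesion_diameter", "lbur", "th_ra_ratio"),
                     config = experimentConfig(), values = NULL) {
  dimension <- match.arg(dimension)
  if (is.null(values))
    values <- switch(dimension,
                     lesion_diameter = seq(15, 35, by = 5),
                     lbur = 2:6,
                     th_ra_ratio = c(10, 5, 3, 1))
  meritTab <- crlbTab <- NULL
  setup <- .studySetup(config)  # sensitivity calibrated once, standard phantom
  stdTotal <- standardTotalActivity(config$totalActivityBq, config$thRaRatio)
  for (vi in seq_along(values)) {
    v <- values[vi]
    phantom <- switch(dimension,
      lesion_diameter = makePelvicPhantom(grid = config$grid,
        lesionDiameterMm = v, totalActivityBq = stdTotal),
      lbur = {
        ratios <- standardUptakeRatios()
        ratios[, "lesion"] <- ratios[, "bone"] * v
        makePelvicPhantom(grid = config$grid,
                          lesionDiameterMm = config$lesionDiameterMm,
                          uptakeRatios = ratios, totalActivityBq = stdTotal)
      },
      th_ra_ratio = makePelvicPhantom(grid = config$grid,
        lesionDiameterMm = config$lesionDiameterMm,
        totalActivityBq = standardTotalActivity(config$totalActivityBq, v)))
    sysmat <- .buildH(phantom, setup, config)
    truth <- regionalUptake(phantom)
    ests <- setNames(vector("list", length(config$methods)), config$methods)
    for (m in config$methods) ests[[m]] <- vector("list", config$nRealizations)
    for (r in seq_len(config$nRealizations)) {
      g <- simulateProjections(sysmat, truth,
                               seed = .deriveSeed(config$seed, 2L + vi, r))
      q <- .quantifyAll(g, sysmat, phantom, setup, config)
      for (m in names(q)) ests[[m]][[r]] <- q[[m]]
    }
    for (m in config$methods) {
      mr <- meritReport(ests[[m]], truth)
      mr$method <- m; mr$value <- v
      meritTab <- rbind(meritTab, mr)
    }
    nsd <- crlbNsd(fisherInformation(sysmat, truth), truth)
    crlbTab <- rbind(crlbTab, data.frame(value = v, parameter = names(nsd),
                                         crlbNsd = as.numeric(nsd)))
  }
  list(merit = meritTab, crlb = crlbTab,
       manifest = list(dimension = dimension, values = values,
                       configHash = .configHash(config), seed = config$seed))
}

#' Virtual imaging trial
#'
#' Samples a patient population (lesion size, location, body scale and
#' regional uptake all randomized), simulates a single matched-model noise
#' realization per patient, quantifies with the configured methods, and
#' reports ensemble NB / NRMSE per region and isotope.
#'
#' @param config An \code{\link{experimentConfig}}; \code{config$nPatients}
#'   patients are sampled.
#' @return List with \code{merit} (per-method ensemble data frame),
#'   \code{patientErrors} (per-patient normalized errors of the
#'   projection-domain method), \code{info} (sampled population summary)
#'   and \code{manifest}.
#' @export
runVit <- function(config = experimentConfig()) {
  setup <- .studySetup(config)  # calibration anchor: standard phantom
  pop <- sampleVitPopulation(config$nPatients,
                             seed = .deriveSeed(config$seed, 10L),
                             config = vitConfig(grid = config$grid))
  truths <- lapply(pop$patients, regionalUptake)
  ests <- list()
  for (m in config$methods) ests[[m]] <- vector("list", config$nPatients)
  for (p in seq_len(config$nPatients)) {
    phantom <- pop$patients[[p]]
    sysmat <- .buildH(phantom, setup, config)
    g <- simulateProjections(sysmat, truths[[p]],
                             seed = .deriveSeed(config$seed, 11L, p))
    q <- .quantifyAll(g, sysmat, phantom, setup, config)
    for (m in names(q)) ests[[m]][[p]] <- q[[m]]
  }
  meritTab <- NULL
  for (m in config$methods) {
    em <- ensembleMerit(ests[[m]], truths)
    em$method <- m
    meritTab <- rbind(meritTab, em)
  }
  K <- length(truths[[1]]@lambdaTh)
  perr <- t(vapply(seq_len(config$nPatients), function(p)
    (.asUptakeVector(ests$mewpdq[[p]]) - uptakeVector(truths[[p]])) /
      uptakeVector(truths[[p]]), numeric(2 * K)))
  list(merit = meritTab, patientErrors = perr, info = pop$info,
       manifest = list(configHash = .configHash(config), seed = config$seed,
                       nPatients = config$nPatients,
                       methods = config$methods))
}

#' Robustness studies: intra-regional heterogeneity and misregistration
#'
#' Heterogeneity: for each mixture weight W, lumpy-textured patients
#' (background/gut/lesion) are simulated in voxel mode and quantified with
#' the homogeneous-VOI system matrix (W = 0 reproduces the homogeneous
#' case bitwise under shared seeds).  Misregistration: the patient is
#' shifted/rotated while estimation keeps the stale VOI definitions and
#' attenuation (the SPECT/CT mismatch design).
#'
#' @param kind \code{"heterogeneity"} or \code{"misregistration"}.
#' @param config An \code{\link{experimentConfig}}.
#' @return List with \code{merit} (per-condition data frame) and
#'   \code{manifest}.
#' @export
runRobustness <- function(kind = c("heterogeneity", "misregistration"),
                          config = experimentConfig()) {
  kind <- match.arg(kind)
  setup <- .studySetup(config)
  sysmat <- .buildH(setup$phantom, setup, config)  # stale/homogeneous model
  truth <- regionalUptake(setup$phantom)
  meritTab <- NULL
  if (kind == "heterogeneity") {
    lumpy <- list(background = c(380, 23), gut = c(140, 16), lesion = c(490, 2))
    for (pat in seq_len(config$nHetPatients)) {
      fhet <- setup$phantom
      for (rn in names(lumpy))
        fhet <- applyLumpyHeterogeneity(fhet, rn, lumpy[[rn]][1], lumpy[[rn]][2],
                                        seed = .deriveSeed(config$seed, 20L + pat,
                                                           match(rn, names(lumpy))))
      for (w in config$hetW) {
        fmix <- mixHeterogeneity(fhet, setup$phantom, w)
        ests <- vector("list", config$nRealizations)
        for (r in seq_len(config$nRealizations)) {
          g <- simulateProjectionsVoxel(fmix, setup$geometry, setup$windows,
                                        setup$detector, setup$spectra,
                                        strayReference = config$strayReference,
                                        seed = .deriveSeed(config$seed, 30L + pat, r))
          ests[[r]] <- runMewPdq(g, sysmat, maxIter = config$emIters,
                                 traceEvery = 0L, logLikEvery = 0L)
        }
        mr <- meritReport(ests, truth)
        mr$W <- w; mr$patient <- pat
        meritTab <- rbind(meritTab, mr)
      }
    }
  } else {
    mkCond <- function(x, y, r) {
      n <- max(length(x), length(y), length(r))
      if (n == 0 || !length(x) || !length(y) || !length(r)) return(NULL)
      data.frame(shiftX = x, shiftY = y, rotDeg = r)
    }
    conds <- rbind(
      mkCond(config$shiftsX, 0, 0),
      mkCond(0, config$shiftsY, 0),
      mkCond(0, 0, config$rotationsDeg))
    if (is.null(conds)) stop("no misregistration conditions configured")
    for (ci in seq_len(nrow(conds))) {
      moved <- applyRigidMisregistration(setup$phantom,
                                         shiftVoxels = c(conds$shiftX[ci],
                                                         conds$shiftY[ci]),
                                         rotationDeg = conds$rotDeg[ci])
      ests <- vector("list", config$nRealizations)
      for (r in seq_len(config$nRealizations)) {
        g <- simulateProjectionsVoxel(moved, setup$geometry, setup$windows,
                                      setup$detector, setup$spectra,
                                      strayReference = config$strayReference,
                                      seed = .deriveSeed(config$seed, 40L + ci, r))
        ests[[r]] <- runMewPdq(g, sysmat, maxIter = config$emIters,
                               traceEvery = 0L, logLikEvery = 0L)
      }
      mr <- meritReport(ests, truth)
      mr$shiftX <- conds$shiftX[ci]; mr$shiftY <- conds$shiftY[ci]
      mr$rotDeg <- conds$rotDeg[ci]
      meritTab <- rbind(meritTab, mr)
    }
  }
  list(merit = meritTab,
       manifest = list(kind = kind, configHash = .configHash(config),
                       seed = config$seed, staleVoi = TRUE))
}
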