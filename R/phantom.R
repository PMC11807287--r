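# Parametric pelvic phantoms: a torso stand-in with four uptake VOIs
# (background, pelvic bone, gut, bone lesion), lumpy intra-regional
# heterogeneity, virtual-imaging-trial population sampling and rigid
# misregistration perturbations.

# effective densities (g/cm^3) used to convert mu/rho into linear attenuation;
# the bone value is a mixed trabecular/cortical convention
.TISSUE_DENSITY <- c(water = 1.0, bone = 1.55)
.REF_ENERGY_KEV <- 140

#' Define an isotropic phantom grid
#'
#' @param n Integer vector of grid dimensions (nx, ny, nz).
#' @param voxelMm Isotropic voxel side length in mm.
#' @return A list with elements \code{n} and \code{voxelMm}.
#' @export
phantomGrid <- function(n = c(128L, 128L, 96L), voxelMm = 2.21) {
  stopifnot(length(n) == 3, all(n >= 4), voxelMm > 0)
  list(n = as.integer(n), voxelMm = voxelMm)
}

#' Standard regional uptake ratios
#'
#' Mean activity-uptake ratios across the four VOIs (background, bone, gut,
#' lesion): 12:30:100:300 for Th-227 and 2:5:25:20 for Ra-223, matching the
#' pattern seen clinically in Ra-223 therapy patients.
#'
#' @return A 2 x 4 matrix with rows \code{Th}, \code{Ra}.
#' @export
standardUptakeRatios <- function() {
  m <- rbind(Th = c(12, 30, 100, 300), Ra = c(2, 5, 25, 20))
  colnames(m) <- c("background", "bone", "gut", "lesion")
  m
}

#' Standard total administered activity split
#'
#' A combined total of 11 MBq split between the isotopes by the global
#' Th:Ra activity ratio (5:1 by default, the ratio at roughly 82 h after
#' administration of pure Th-227).
#'
#' @param totalBq Combined total activity (Bq).
#' @param thRaRatio Global Th:Ra activity ratio.
#' @return Named vector \code{c(Th = , Ra = )} in Bq.
#' @export
standardTotalActivity <- function(totalBq = 11e6, thRaRatio = 5)
  c(Th = totalBq * thRaRatio / (1 + thRaRatio), Ra = totalBq / (1 + thRaRatio))

# voxel-centre coordinates (mm, origin at the grid centre) along one axis
.axisCoords <- function(n, voxelMm) (seq_len(n) - (n + 1) / 2) * voxelMm

# torso geometry masks; all linear dimensions scale with bodyScale
.pelvicMasks <- function(grid, bodyScale = 1) {
  n <- grid$n; v <- grid$voxelMm; s <- bodyScale
  x <- .axisCoords(n[1], v); y <- .axisCoords(n[2], v); z <- .axisCoords(n[3], v)
  X <- array(rep(x, times = n[2] * n[3]), dim = n)
  Y <- array(rep(rep(y, each = n[1]), times = n[3]), dim = n)
  Z <- array(rep(z, each = n[1] * n[2]), dim = n)
  bodyA <- 120 * s; bodyB <- 85 * s
  if (bodyA > (n[1] / 2 - 1) * v || bodyB > (n[2] / 2 - 1) * v)
    stop("body does not fit the grid: increase the grid or reduce bodyScale")
  # elliptical-cylinder torso; the axial extent stops two voxels short of the
  # grid so that small rigid rotations keep the body inside the field of view
  body <- (X / bodyA)^2 + (Y / bodyB)^2 <= 1 & abs(Z) <= (n[3] / 2 - 2) * v
  ell <- function(cx, cy, cz, ax, ay, az)
    ((X - cx) / ax)^2 + ((Y - cy) / ay)^2 + ((Z - cz) / az)^2 <= 1
  bone <- ell(60 * s, 10 * s, 0, 50 * s, 42 * s, 52 * s) |
          ell(-60 * s, 10 * s, 0, 50 * s, 42 * s, 52 * s)
  gut <- ell(0, -42 * s, 8 * s, 55 * s, 24 * s, 40 * s)
  list(body = body, bone = bone & body, gut = gut & body,
       X = X, Y = Y, Z = Z)
}

.sphereMask <- function(masks, centerMm, diameterMm) {
  r <- diameterMm / 2
  d2 <- (masks$X - centerMm[1])^2 + (masks$Y - centerMm[2])^2 +
    (masks$Z - centerMm[3])^2
  m <- d2 <= r^2
  if (!any(m)) m[which.min(d2)] <- TRUE  # sub-voxel sphere: keep centre voxel
  m
}

#' Generate a parametric pelvic phantom
#'
#' Builds a torso phantom with an elliptical-cylinder body, a two-lobed
#' pelvic bone, a gut compartment, and a spherical lesion embedded in bone.
#' Attenuation is water-like in soft tissue (including the lesion and gut)
#' and bone-like in bone, at the 140 keV reference energy.  Activity maps
#' are constant within each VOI.
#'
#' When \code{uptake} is not given, absolute regional concentrations are
#' derived from \code{uptakeRatios} by scaling each isotope so that its total
#' phantom activity equals \code{totalActivityBq}.
#'
#' @param grid A \code{\link{phantomGrid}}.
#' @param lesionDiameterMm Lesion diameter in mm.
#' @param uptake Optional \code{RegionalUptake} of absolute concentrations
#'   (Bq/mL); overrides the ratio/total scaling.
#' @param uptakeRatios 2 x 4 matrix of regional uptake ratios (rows Th, Ra).
#' @param totalActivityBq Named vector \code{c(Th=, Ra=)} of per-isotope
#'   total activity (Bq) used to scale the ratios.
#' @param bodyScale Dimensionless body size factor.
#' @param lesionCenterMm Lesion centre (mm, grid-centred coordinates);
#'   defaults to the centre of the right bone lobe.
#' @return A \code{\link{Phantom-class}} object.
#' @export
makePelvicPhantom <- function(grid = phantomGrid(),
                              lesionDiameterMm = 33.75,
                              uptake = NULL,
                              uptakeRatios = standardUptakeRatios(),
                              totalActivityBq = standardTotalActivity(),
                              bodyScale = 1,
                              lesionCenterMm = NULL) {
  stopifnot(lesionDiameterMm > 0)
  masks <- .pelvicMasks(grid, bodyScale)
  if (is.null(lesionCenterMm))
    lesionCenterMm <- c(60, 10, 0) * bodyScale
  lesion <- .sphereMask(masks, lesionCenterMm, lesionDiameterMm)
  outside <- lesion & !masks$bone
  if (any(outside))
    stop(sprintf(paste("lesion of diameter %.4g mm at (%g, %g, %g) mm is not",
                       "fully inside the bone support: %d voxels overflow"),
                 lesionDiameterMm, lesionCenterMm[1], lesionCenterMm[2],
                 lesionCenterMm[3], sum(outside)))
  labels <- array(0L, dim = grid$n)
  labels[masks$body] <- 1L
  labels[masks$gut] <- 3L
  labels[masks$bone] <- 2L
  labels[lesion] <- 4L
  voiNames <- c("background", "bone", "gut", "lesion")

  muW <- massAttenuationMuRho(.REF_ENERGY_KEV, "water") * .TISSUE_DENSITY["water"]
  muB <- massAttenuationMuRho(.REF_ENERGY_KEV, "bone") * .TISSUE_DENSITY["bone"]
  muSoft <- array(0, dim = grid$n); muBone <- array(0, dim = grid$n)
  softMask <- labels %in% c(1L, 3L, 4L)  # lesion and gut are soft-tissue-like
  muSoft[softMask] <- muW
  muBone[labels == 2L] <- muB

  voxVolMl <- (grid$voxelMm / 10)^3
  nVox <- tabulate(labels, nbins = 4L)
  if (any(nVox == 0))
    stop("empty VOI on this grid: ", paste(voiNames[nVox == 0], collapse = ", "))
  if (is.null(uptake)) {
    vols <- nVox * voxVolMl
    lamTh <- uptakeRatios["Th", ] * totalActivityBq[["Th"]] /
      sum(uptakeRatios["Th", ] * vols)
    lamRa <- uptakeRatios["Ra", ] * totalActivityBq[["Ra"]] /
      sum(uptakeRatios["Ra", ] * vols)
    uptake <- regionalUptakeValues(lamTh, lamRa, names = voiNames)
  }
  actTh <- array(0, dim = grid$n); actRa <- array(0, dim = grid$n)
  for (k in 1:4) {
    sel <- labels == k
    actTh[sel] <- uptake@lambdaTh[k]
    actRa[sel] <- uptake@lambdaRa[k]
  }
  new("Phantom", voxelMm = grid$voxelMm, voiLabels = labels,
      voiNames = voiNames, muSoft = muSoft, muBone = muBone,
      activityTh = actTh, activityRa = actRa, uptake = uptake)
}

#' Regional mean uptake computed from the voxel maps
#'
#' Direct voxel averaging of the activity maps over each VOI; for a freshly
#' generated phantom this reproduces the requested uptake exactly.
#'
#' @param phantom A \code{Phantom}.
#' @return A \code{RegionalUptake}.
#' @export
phantomRegionalMeans <- function(phantom) {
  K <- nRegions(phantom)
  lamTh <- lamRa <- numeric(K)
  for (k in seq_len(K)) {
    sel <- phantom@voiLabels == k
    lamTh[k] <- mean(phantom@activityTh[sel])
    lamRa[k] <- mean(phantom@activityRa[sel])
  }
  regionalUptakeValues(lamTh, lamRa, names = phantom@voiNames)
}

#' Impose lumpy intra-regional heterogeneity
#'
#' Replaces the homogeneous uptake of one VOI by a sum-of-Gaussians lumpy
#' texture: the lump count is Poisson with the given mean, lump centres are
#' uniform over the region support, each lump is an isotropic Gaussian of the
#' given width (truncated at 4 sigma), the texture is masked by the region
#' support, and its magnitude is rescaled so the regional mean equals the
#' original uptake exactly.  The same spatial texture modulates both
#' isotopes.  If zero lumps are drawn the region is left homogeneous
#' (documented fallback).
#'
#' @param phantom A \code{Phantom} with homogeneous uptake in the region.
#' @param region VOI index or name.
#' @param meanLumps Mean number of lumps (Poisson mean).
#' @param lumpWidthMm Gaussian lump width sigma (mm).
#' @param seed Optional integer seed for reproducibility.
#' @return A \code{Phantom} with the heterogeneous region.
#' @export
applyLumpyHeterogeneity <- function(phantom, region, meanLumps, lumpWidthMm,
                                    seed = NULL) {
  stopifnot(meanLumps >= 0, lumpWidthMm > 0)
  if (is.character(region)) region <- match(region, phantom@voiNames)
  if (is.na(region) || region < 1 || region > nRegions(phantom))
    stop("unknown region")
  sel <- phantom@voiLabels == region
  if (!any(sel)) stop("region ", region, " is empty")
  for (iso in c("activityTh", "activityRa")) {
    vals <- slot(phantom, iso)[sel]
    if (diff(range(vals)) > 1e-9 * (mean(vals) + 1e-300))
      stop("region must have homogeneous uptake before applying the lumpy model")
  }
  if (!is.null(seed)) set.seed(seed)
  P <- rpois(1, meanLumps)
  if (P == 0) return(phantom)

  n <- dim(phantom@voiLabels); v <- phantom@voxelMm
  idx <- which(sel)
  pick <- idx[sample.int(length(idx), P, replace = TRUE)]
  ai <- arrayInd(pick, n)
  centers <- sweep(ai + matrix(runif(3 * P) - 0.5, ncol = 3), 2,
                   (n + 1) / 2) * v  # mm, grid-centred, jittered in-voxel
  x <- .axisCoords(n[1], v); y <- .axisCoords(n[2], v); z <- .axisCoords(n[3], v)
  field <- array(0, dim = n)
  cut <- 4 * lumpWidthMm
  for (p in seq_len(P)) {
    ix <- which(abs(x - centers[p, 1]) <= cut)
    iy <- which(abs(y - centers[p, 2]) <= cut)
    iz <- which(abs(z - centers[p, 3]) <= cut)
    if (!length(ix) || !length(iy) || !length(iz)) next
    gx <- exp(-(x[ix] - centers[p, 1])^2 / (2 * lumpWidthMm^2))
    gy <- exp(-(y[iy] - centers[p, 2])^2 / (2 * lumpWidthMm^2))
    gz <- exp(-(z[iz] - centers[p, 3])^2 / (2 * lumpWidthMm^2))
    field[ix, iy, iz] <- field[ix, iy, iz] + c(outer(gx, gy) %o% gz)
  }
  fsel <- field[sel]
  if (sum(fsel) == 0) return(phantom)
  shape <- fsel * (length(fsel) / sum(fsel))  # mean(shape) == 1
  out <- phantom
  out@activityTh[sel] <- phantom@uptake@lambdaTh[region] * shape
  out@activityRa[sel] <- phantom@uptake@lambdaRa[region] * shape
  validObject(out)
  out
}

#' Mix a heterogeneous and a homogeneous phantom
#'
#' Voxelwise convex combination \code{W * f_het + (1 - W) * f_hom} of the
#' activity maps of two phantoms sharing a grid, labels and regional means.
#' Regional means are invariant in \code{W}.
#'
#' @param fhet,fhom Phantoms with heterogeneous / homogeneous uptake.
#' @param W Mixture weight in \code{[0, 1]}.
#' @return A \code{Phantom}.
#' @export
mixHeterogeneity <- function(fhet, fhom, W) {
  stopifnot(W >= 0, W <= 1)
  if (!identical(dim(fhet@voiLabels), dim(fhom@voiLabels)) ||
      !isTRUE(all.equal(fhet@voxelMm, fhom@voxelMm)))
    stop("phantoms do not share a grid")
  if (!identical(fhet@voiLabels, fhom@voiLabels))
    stop("phantoms do not share VOI labels")
  out <- fhom
  out@activityTh <- W * fhet@activityTh + (1 - W) * fhom@activityTh
  out@activityRa <- W * fhet@activityRa + (1 - W) * fhom@activityRa
  out
}

#' Virtual-imaging-trial sampling configuration
#'
#' Population parameters: lesion diameter ~ N(33.75, 12.64^2) mm truncated
#' to \code{[minDiameterMm, maxDiameterMm]}; per-region uptake ratios of each
#' isotope drawn independently ~ N(mean ratio, (10\% of mean)^2) truncated at
#' 0; lesion centre uniform within the pelvic bone subject to containment;
#' body scale lognormal (median 1, log-SD 0.08) truncated to
#' \code{bodyScaleRange} so every sampled torso fits the imaging grid;
#' per-isotope totals scaled so the mean Th:Ra total-activity ratio is 5:1
#' at 11 MBq combined.
#'
#' @param grid Phantom grid for the population.
#' @param ... Overrides of the listed defaults.
#' @return Configuration list.
#' @export
vitConfig <- function(grid = phantomGrid(), ...) {
  cfg <- list(grid = grid,
              meanDiameterMm = 33.75, sdDiameterMm = 12.64,
              minDiameterMm = 10, maxDiameterMm = 60,
              uptakeRatios = standardUptakeRatios(), ratioCv = 0.10,
              totalActivityBq = standardTotalActivity(11e6, 5),
              bodyScaleLogSd = 0.08, bodyScaleRange = c(0.85, 1.15),
              maxRetries = 200L)
  modifyList(cfg, list(...))
}

.truncNorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rnorm(1, mean[i], sd[i])
      if (x >= lower && x <= upper) break
    }
    out[i] <- x
  }
  out
}

#' Sample a virtual-imaging-trial patient population
#'
#' @param nPatients Number of patients (>= 1).
#' @param seed Integer seed; the population is byte-identical under a fixed
#'   seed.
#' @param config A \code{\link{vitConfig}}.
#' @return List with \code{patients} (list of \code{Phantom}, each carrying
#'   its true \code{RegionalUptake}) and \code{info} (data frame of sampled
#'   diameters, body scales and lesion centres).
#' @export
sampleVitPopulation <- function(nPatients, seed, config = vitConfig()) {
  stopifnot(nPatients >= 1)
  set.seed(seed)
  patients <- vector("list", nPatients)
  info <- data.frame(diameterMm = numeric(nPatients),
                     bodyScale = numeric(nPatients),
                     cx = numeric(nPatients), cy = numeric(nPatients),
                     cz = numeric(nPatients))
  meanRatios <- config$uptakeRatios
  for (p in seq_len(nPatients)) {
    d <- .truncNorm(1, config$meanDiameterMm, config$sdDiameterMm,
                    config$minDiameterMm, config$maxDiameterMm)
    repeat {
      bs <- rlnorm(1, 0, config$bodyScaleLogSd)
      if (bs >= config$bodyScaleRange[1] && bs <= config$bodyScaleRange[2]) break
    }
    masks <- .pelvicMasks(config$grid, bs)
    boneIdx <- which(masks$bone)
    center <- NULL
    for (try in seq_len(config$maxRetries)) {
      cand <- boneIdx[sample.int(length(boneIdx), 1)]
      ai <- arrayInd(cand, config$grid$n)
      cmm <- (as.numeric(ai) - (config$grid$n + 1) / 2) * config$grid$voxelMm
      sph <- .sphereMask(masks, cmm, d)
      if (!any(sph & !masks$bone)) { center <- cmm; break }
    }
    if (is.null(center))
      stop(sprintf("could not place a %.3g mm lesion inside the bone after %d retries",
                   d, config$maxRetries))
    ratios <- meanRatios
    for (r in seq_len(nrow(ratios)))
      ratios[r, ] <- .truncNorm(ncol(ratios), meanRatios[r, ],
                                config$ratioCv * meanRatios[r, ], lower = 0)
    # scale by the MEAN-ratio normalization so sampled regional variability
    # survives and totals hit the target on average
    ph0labels <- NULL
    phantom <- local({
      lesion <- .sphereMask(masks, center, d)
      labels <- array(0L, dim = config$grid$n)
      labels[masks$body] <- 1L; labels[masks$gut] <- 3L
      labels[masks$bone] <- 2L; labels[lesion] <- 4L
      vols <- tabulate(labels, 4L) * (config$grid$voxelMm / 10)^3
      cTh <- config$totalActivityBq[["Th"]] / sum(meanRatios["Th", ] * vols)
      cRa <- config$totalActivityBq[["Ra"]] / sum(meanRatios["Ra", ] * vols)
      up <- regionalUptakeValues(ratios["Th", ] * cTh, ratios["Ra", ] * cRa,
                                 names = c("background", "bone", "gut", "lesion"))
      makePelvicPhantom(grid = config$grid, lesionDiameterMm = d, uptake = up,
                        bodyScale = bs, lesionCenterMm = center)
    })
    patients[[p]] <- phantom
    info[p, ] <- c(d, bs, center)
  }
  list(patients = patients, info = info)
}

# trilinear resampling of a 3D array at fractional (1-based) indices;
# points outside the grid read 0
.resample3 <- function(arr, ci, cj, ck) {
  n <- dim(arr)
  i0 <- floor(ci); j0 <- floor(cj); k0 <- floor(ck)
  fi <- ci - i0; fj <- cj - j0; fk <- ck - k0
  out <- numeric(length(ci))
  at <- function(ii, jj, kk) {
    ok <- ii >= 1 & ii <= n[1] & jj >= 1 & jj <= n[2] & kk >= 1 & kk <= n[3]
    v <- numeric(length(ii))
    v[ok] <- arr[cbind(ii[ok], jj[ok], kk[ok])]
    v
  }
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di) fi else 1 - fi) * (if (dj) fj else 1 - fj) *
         (if (dk) fk else 1 - fk)
    nz <- w > 0
    if (!any(nz)) next
    out[nz] <- out[nz] + w[nz] * at(i0[nz] + di, j0[nz] + dj, k0[nz] + dk)
  }
  out
}

#' Apply a rigid misregistration to the patient
#'
#' Shifts the patient by the given number of voxels along x and y and/or
#' rotates it about the y axis, resampling the activity and attenuation maps
#' trilinearly.  The VOI label map is deliberately NOT transformed: later
#' estimation steps that use the stale VOI definitions reproduce a
#' SPECT/CT misregistration.  The stored ground-truth uptake is unchanged
#' (the patient moved; its uptake did not).
#'
#' @param phantom A \code{Phantom}.
#' @param shiftVoxels Length-2 numeric (x, y) shift in voxels.
#' @param rotationDeg Rotation about the y axis in degrees.
#' @return A \code{Phantom} with transformed activity/attenuation maps.
#' @export
applyRigidMisregistration <- function(phantom, shiftVoxels = c(0, 0),
                                      rotationDeg = 0) {
  stopifnot(length(shiftVoxels) == 2)
  if (all(shiftVoxels == 0) && rotationDeg == 0) return(phantom)
  n <- dim(phantom@voiLabels)
  th <- rotationDeg * pi / 180
  cx <- (n[1] + 1) / 2; cz <- (n[3] + 1) / 2
  # forward transform: rotate about y, then shift (in voxel units)
  fwd <- function(i, j, k) {
    di <- i - cx; dk <- k - cz
    cbind(cx + cos(th) * di + sin(th) * dk + shiftVoxels[1],
          j + shiftVoxels[2],
          cz - sin(th) * di + cos(th) * dk)
  }
  body <- which(phantom@voiLabels > 0L | (phantom@muSoft + phantom@muBone) > 0)
  ai <- arrayInd(body, n)
  rng <- apply(ai, 2, range)
  corners <- as.matrix(expand.grid(rng[, 1], rng[, 2], rng[, 3]))
  fc <- fwd(corners[, 1], corners[, 2], corners[, 3])
  if (any(fc[, 1] < 1 | fc[, 1] > n[1] | fc[, 2] < 1 | fc[, 2] > n[2] |
          fc[, 3] < 1 | fc[, 3] > n[3]))
    stop("transform clips the body at the grid boundary")
  idx <- arrayInd(seq_len(prod(n)), n)
  # inverse transform of every target voxel
  i <- idx[, 1] - shiftVoxels[1]; j <- idx[, 2] - shiftVoxels[2]; k <- idx[, 3]
  di <- i - cx; dk <- k - cz
  si <- cx + cos(th) * di - sin(th) * dk
  sk <- cz + sin(th) * di + cos(th) * dk
  out <- phantom
  for (s in c("activityTh", "activityRa", "muSoft", "muBone")) {
    res <- .resample3(slot(phantom, s), si, j, sk)
    slot(out, s) <- array(pmax(res, 0), dim = n)
  }
  out
}
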