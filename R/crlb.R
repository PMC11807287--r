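# Fisher information, CRLB-derived NSD, energy-window subset analysis and
# the NB/NSD/NRMSE figures of merit (plus their ensemble variants).

.windowRows <- function(sysmat, windowSubset) {
  pd <- sysmat@projDim
  Ms <- prod(pd[1:3])
  windowSubset <- as.integer(windowSubset)
  if (any(windowSubset < 1 | windowSubset > pd[4]))
    stop("window subset out of range")
  as.vector(outer(seq_len(Ms), (windowSubset - 1L) * Ms, "+"))
}

#' Poisson Fisher information of the composite uptake parameter
#'
#' \code{F_ab = sum_m H_ma H_mb / ((H lambda)_m + psi_m)} over the projection
#' rows of the chosen energy windows, for the composite 2K-dimensional
#' (Th, Ra) parameter.
#'
#' @param sysmat \code{SystemMatrixSet}.
#' @param lambda 2K-vector or \code{RegionalUptake} evaluation point.
#' @param windowSubset Integer indices of the windows to retain (default:
#'   all).
#' @return A \code{\link{FisherInfo-class}}.
#' @export
fisherInformation <- function(sysmat, lambda, windowSubset = NULL) {
  lambda <- .lambdaFromInput(lambda, sysmat)
  if (is.null(windowSubset)) windowSubset <- seq_len(sysmat@projDim[4])
  rows <- .windowRows(sysmat, windowSubset)
  H <- cbind(sysmat@HTh, sysmat@HRa)[rows, , drop = FALSE]
  mu <- as.numeric(H %*% lambda) + sysmat@psi[rows]
  if (any(mu <= 0))
    stop("retained bin with zero mean; use psi > 0 or drop the window")
  Fm <- crossprod(H / sqrt(mu))
  Fm <- (Fm + t(Fm)) / 2
  K <- ncol(sysmat@HTh)
  dimnames(Fm) <- rep(list(c(paste0("Th.", sysmat@voiNames),
                             paste0("Ra.", sysmat@voiNames))), 2)
  new("FisherInfo", matrix = Fm, lambda = lambda,
      windowSubset = as.integer(windowSubset))
}

#' CRLB-derived normalized standard deviation
#'
#' The square root of the diagonal of the inverse Fisher information,
#' normalized by the ground-truth uptake: the lowest NSD attainable by an
#' unbiased estimator.
#'
#' @param fisher \code{FisherInfo}.
#' @param lambdaTrue Ground-truth 2K-vector or \code{RegionalUptake}
#'   (defaults to the Fisher evaluation point).
#' @param pseudoInverse If TRUE, fall back to an eigenvalue-floored
#'   pseudo-inverse for singular matrices (with a warning).
#' @return Named vector of 2K CRLB-NSD fractions.
#' @export
crlbNsd <- function(fisher, lambdaTrue = NULL, pseudoInverse = FALSE) {
  Fm <- fisher@matrix
  if (is.null(lambdaTrue)) lambdaTrue <- fisher@lambda
  if (is(lambdaTrue, "RegionalUptake")) lambdaTrue <- uptakeVector(lambdaTrue)
  cov <- tryCatch(solve(Fm), error = function(e) NULL)
  if (is.null(cov) || any(diag(cov) < 0)) {
    if (!pseudoInverse)
      stop("Fisher information is singular; enable pseudoInverse to proceed")
    warning("singular Fisher information: using eigenvalue-floored pseudo-inverse")
    eg <- eigen(Fm, symmetric = TRUE)
    vals <- pmax(eg$values, 1e-12 * max(eg$values))
    cov <- eg$vectors %*% diag(1 / vals, nrow = length(vals)) %*% t(eg$vectors)
  }
  out <- sqrt(pmax(diag(cov), 0)) / lambdaTrue
  names(out) <- colnames(Fm)
  out
}

#' CRLB-NSD across nested energy-window subsets
#'
#' Computes the CRLB-derived NSD for each subset in a nested sequence of
#' energy-window sets; along nested subsets the NSD is non-increasing for
#' every parameter (information monotonicity).
#'
#' @param sysmat \code{SystemMatrixSet}.
#' @param lambda Evaluation point (truth).
#' @param subsets List of integer window-index vectors, default
#'   \code{list(1, 1:2, 1:3, 1:4)}.
#' @param pseudoInverse Passed to \code{\link{crlbNsd}} (single-window
#'   dual-isotope problems can be near-singular).
#' @return Data frame with columns \code{subset}, \code{parameter},
#'   \code{isotope}, \code{region}, \code{nsd}.
#' @export
windowSubsetStudy <- function(sysmat, lambda,
                              subsets = list(1L, 1:2, 1:3, 1:4),
                              pseudoInverse = TRUE) {
  nested <- all(vapply(seq_along(subsets)[-1], function(i)
    all(subsets[[i - 1]] %in% subsets[[i]]), logical(1)))
  if (!nested)
    warning("window subsets are not nested; NSD monotonicity is not guaranteed")
  out <- NULL
  for (s in subsets) {
    fi <- fisherInformation(sysmat, lambda, windowSubset = s)
    nsd <- crlbNsd(fi, lambda, pseudoInverse = pseudoInverse)
    K <- length(nsd) / 2
    out <- rbind(out, data.frame(
      subset = paste(s, collapse = "+"),
      parameter = names(nsd),
      isotope = rep(c("Th", "Ra"), each = K),
      region = rep(sysmat@voiNames, 2),
      nsd = as.numeric(nsd), row.names = NULL))
  }
  out
}

.estimateMatrix <- function(estimates) {
  if (!is.list(estimates) || !is.null(estimates$lambdaTh))
    estimates <- list(estimates)
  vecs <- lapply(estimates, .asUptakeVector)
  do.call(rbind, vecs)
}

#' Figures of merit over noise realizations
#'
#' For a single ground truth and repeated noise realizations:
#' normalized bias \code{NB = (mean(est) - truth)/truth}, normalized
#' standard deviation \code{NSD = sd(est)/truth} (population, 1/n
#' convention) and \code{NRMSE = rms(est - truth)/truth}; with this
#' convention \code{NRMSE^2 = NB^2 + NSD^2} exactly.
#'
#' @param estimates List of \code{UptakeEstimate} from repeated realizations.
#' @param truth \code{RegionalUptake} ground truth (all entries nonzero).
#' @return Data frame with columns \code{isotope}, \code{region}, \code{nb},
#'   \code{nsd}, \code{nrmse}, \code{n}.
#' @export
meritReport <- function(estimates, truth) {
  est <- .estimateMatrix(estimates)
  tru <- uptakeVector(truth)
  if (any(tru == 0)) stop("zero ground-truth uptake: normalization undefined")
  n <- nrow(est)
  K <- length(tru) / 2
  nb <- (colMeans(est) - tru) / tru
  nsd <- if (n > 1) apply(est, 2, function(x) sqrt(mean((x - mean(x))^2))) / tru
         else rep(NA_real_, length(tru))
  nrmse <- sqrt(colMeans(sweep(est, 2, tru)^2)) / tru
  data.frame(isotope = rep(c("Th", "Ra"), each = K),
             region = rep(names(truth@lambdaTh), 2),
             nb = nb, nsd = nsd, nrmse = nrmse, n = n, row.names = NULL)
}

#' Ensemble figures of merit over a patient population
#'
#' Each patient contributes one realization with its own ground truth; the
#' per-patient normalized error \code{e = (est - truth)/truth} is aggregated
#' across patients: ensemble NB is the signed mean of \code{e} (reported
#' with its absolute value alongside) and ensemble NRMSE is the rms of
#' \code{e}.
#'
#' @param estimates List of \code{UptakeEstimate}, one per patient.
#' @param truths List of \code{RegionalUptake}, one per patient.
#' @return Data frame with columns \code{isotope}, \code{region},
#'   \code{ensembleNb}, \code{absEnsembleNb}, \code{ensembleNrmse},
#'   \code{nPatients}.
#' @export
ensembleMerit <- function(estimates, truths) {
  stopifnot(length(estimates) == length(truths), length(estimates) >= 1)
  K <- length(truths[[1]]@lambdaTh)
  errs <- matrix(NA_real_, nrow = length(estimates), ncol = 2 * K)
  for (p in seq_along(estimates)) {
    tru <- uptakeVector(truths[[p]])
    if (any(tru == 0)) stop("zero ground-truth uptake for patient ", p)
    errs[p, ] <- (.asUptakeVector(estimates[[p]]) - tru) / tru
  }
  data.frame(isotope = rep(c("Th", "Ra"), each = K),
             region = rep(names(truths[[1]]@lambdaTh), 2),
             ensembleNb = colMeans(errs),
             absEnsembleNb = abs(colMeans(errs)),
             ensembleNrmse = sqrt(colMeans(errs^2)),
             nPatients = length(estimates), row.names = NULL)
}
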