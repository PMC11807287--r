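# Joint maximum-likelihood EM estimation of regional Th-227 and Ra-223
# uptake from multi-window projections on the VOI basis.

.lambdaFromInput <- function(lambda, sysmat) {
  K <- ncol(sysmat@HTh)
  if (is(lambda, "RegionalUptake")) lambda <- uptakeVector(lambda)
  if (length(lambda) != 2 * K)
    stop("lambda must be a 2K-vector (Th block then Ra block)")
  if (any(lambda < 0)) stop("lambda must be non-negative")
  lambda
}

.countsFromInput <- function(g, sysmat) {
  if (is(g, "ProjectionData")) g <- counts(g)
  M <- nrow(sysmat@HTh)
  if (length(g) != M) stop("projection data length does not match H")
  if (any(g < 0)) stop("counts must be non-negative")
  if (any(g != round(g))) stop("counts must be integer-valued")
  g
}

#' Poisson log-likelihood of projection data
#'
#' \code{sum_m [ g_m log((H lambda)_m + psi_m) - ((H lambda)_m + psi_m) ]};
#' the log-factorial constant is dropped.  Bins with zero mean contribute 0
#' when \code{g_m = 0} and \code{-Inf} (with a warning) when \code{g_m > 0}.
#'
#' @param g \code{ProjectionData} or counts vector.
#' @param sysmat \code{SystemMatrixSet}.
#' @param lambda Composite 2K uptake vector or \code{RegionalUptake}.
#' @return Scalar log-likelihood (up to the dropped constant).
#' @export
poissonLogLik <- function(g, sysmat, lambda) {
  lambda <- .lambdaFromInput(lambda, sysmat)
  g <- .countsFromInput(g, sysmat)
  K <- ncol(sysmat@HTh)
  mu <- as.numeric(sysmat@HTh %*% lambda[seq_len(K)] +
                   sysmat@HRa %*% lambda[K + seq_len(K)]) + sysmat@psi
  pos <- mu > 0
  if (any(!pos & g > 0)) {
    warning("bins with zero model mean but positive counts: log-likelihood is -Inf")
    return(-Inf)
  }
  sum(g[pos] * log(mu[pos]) - mu[pos])
}

#' One joint EM update of the regional uptake
#'
#' The multiplicative update
#' \code{lambda_k <- lambda_k * [sum_m H_mk g_m / ((H lambda)_m + psi_m)] /
#' [sum_m H_mk]}, applied to both isotope blocks with the shared composite
#' denominator.  Non-negativity is preserved and exact zeros stay zero.
#' Bins whose model mean underflows (below 1e-30) are skipped in the ratio
#' sum.
#'
#' @inheritParams poissonLogLik
#' @param lambda Current iterate (2K-vector).
#' @return Updated 2K-vector.
#' @export
emUpdate <- function(lambda, g, sysmat) {
  lambda <- .lambdaFromInput(lambda, sysmat)
  g <- .countsFromInput(g, sysmat)
  H <- cbind(sysmat@HTh, sysmat@HRa)
  sens <- colSums(H)
  if (any(sens <= 0))
    stop("zero-sensitivity column(s): ", paste(which(sens <= 0), collapse = ","))
  mu <- as.numeric(H %*% lambda) + sysmat@psi
  ratio <- numeric(length(mu))
  ok <- mu >= 1e-30
  ratio[ok] <- g[ok] / mu[ok]
  if (any(!ok & g > 0))
    stop("bins with vanishing model mean but positive counts")
  lambda * as.numeric(crossprod(H, ratio)) / sens
}

#' Joint projection-domain quantification of Th-227 and Ra-223
#'
#' Runs the joint EM iteration from a flat positive initialization until a
#' fixed iteration count (default 1000) or until the maximal relative
#' per-iteration change falls below \code{tol} (set \code{tol = 0} for the
#' fixed-iteration protocol).  The log-likelihood is non-decreasing across
#' iterations.
#'
#' @inheritParams poissonLogLik
#' @param init Optional initial 2K-vector; default is flat across VOIs with
#'   total matched to \code{(sum(g) - sum(psi))} divided by the total
#'   sensitivity, floored at a small positive value.
#' @param maxIter Maximum number of EM iterations.
#' @param tol Early-stopping relative-change tolerance (0 disables).
#' @param traceEvery Record an estimate snapshot every this many iterations
#'   (0 disables snapshots; the final estimate is always recorded).
#' @param logLikEvery Record the log-likelihood every this many iterations
#'   (1 = every iteration; 0 disables except first/last).
#' @return An \code{\link{UptakeEstimate-class}}.
#' @export
runMewPdq <- function(g, sysmat, init = NULL, maxIter = 1000L, tol = 0,
                      traceEvery = 50L, logLikEvery = 1L) {
  g <- .countsFromInput(g, sysmat)
  K <- ncol(sysmat@HTh)
  H <- cbind(sysmat@HTh, sysmat@HRa)
  sens <- colSums(H)
  if (any(sens <= 0))
    stop("zero-sensitivity column(s): ", paste(which(sens <= 0), collapse = ","))
  psi <- sysmat@psi
  if (is.null(init)) {
    tot <- max(sum(g) - sum(psi), 1e-6 * sum(g) + 1e-12)
    init <- rep(tot / sum(sens), 2 * K)
    init <- pmax(init, 1e-12)
  }
  lambda <- .lambdaFromInput(init, sysmat)

  doTrace <- traceEvery > 0
  traceRows <- if (doTrace) unique(c(seq(traceEvery, maxIter, by = traceEvery),
                                     maxIter)) else maxIter
  trace <- matrix(NA_real_, nrow = length(traceRows), ncol = 2 * K)
  llIters <- if (logLikEvery > 0)
    unique(c(1L, seq(logLikEvery, maxIter, by = logLikEvery), maxIter)) else
    unique(c(1L, maxIter))
  ll <- numeric(length(llIters))
  llAt <- 1L
  metric <- Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxIter)) {
    mu <- as.numeric(H %*% lambda) + psi
    ok <- mu >= 1e-30
    if (any(!ok & g > 0))
      stop("vanishing model mean with positive counts at iteration ", iter)
    ratio <- numeric(length(mu))
    ratio[ok] <- g[ok] / mu[ok]
    newLambda <- lambda * as.numeric(crossprod(H, ratio)) / sens
    if (any(!is.finite(newLambda)))
      stop("non-finite iterate at iteration ", iter)
    if (llAt <= length(llIters) && iter == llIters[llAt]) {
      ll[llAt] <- sum(g[ok] * log(mu[ok])) - sum(mu)
      llAt <- llAt + 1L
    }
    metric <- max(abs(newLambda - lambda) / pmax(lambda, 1e-12))
    lambda <- newLambda
    if (doTrace && iter %in% traceRows)
      trace[match(iter, traceRows), ] <- lambda
    if (tol > 0 && metric < tol) { converged <- TRUE; break }
  }
  if (iter < maxIter) {  # early stop: truncate records
    keep <- traceRows <= iter
    if (!any(traceRows == iter)) {
      trace <- rbind(trace[keep, , drop = FALSE], lambda)
      traceRows <- c(traceRows[keep], iter)
    } else {
      trace <- trace[keep, , drop = FALSE]
      traceRows <- traceRows[keep]
    }
    llKeep <- llIters <= iter
    ll <- ll[llKeep]; llIters <- llIters[llKeep]
  }
  nm <- sysmat@voiNames
  new("UptakeEstimate",
      lambdaTh = stats::setNames(lambda[seq_len(K)], nm),
      lambdaRa = stats::setNames(lambda[K + seq_len(K)], nm),
      logLik = ll, logLikIters = as.numeric(llIters),
      trace = trace, traceIters = as.numeric(traceRows),
      nIter = as.integer(iter), converged = converged,
      convergenceMetric = metric)
}
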