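test_that("Poisson log-likelihood matches closed forms and a brute-force oracle", {
  # single bin, H = 2, psi = 1, lambda = 2, g = 5: 5 log 5 - 5
  sb <- singleBinSysmat(h = 2, psi = 1)
  expect_equal(poissonLogLik(5, sb, c(2, 0)), 5 * log(5) - 5)
  # g equal to psi with lambda = 0: sum g log psi - psi
  sm <- toySysmat(seed = 4, psi = c(2, 3))
  g <- sm@psi
  expect_equal(poissonLogLik(g, sm, rep(0, 4)),
               sum(g * log(sm@psi) - sm@psi))
  # brute-force per-bin summation oracle on random points
  set.seed(8)
  for (r in 1:5) {
    lam <- runif(4, 0, 5)
    gg <- rpois(nrow(sm@HTh), 4)
    H <- cbind(sm@HTh, sm@HRa)
    mu <- as.numeric(H %*% lam) + sm@psi
    oracle <- sum(vapply(seq_along(gg), function(m)
      gg[m] * log(mu[m]) - mu[m], numeric(1)))
    expect_equal(poissonLogLik(gg, sm, lam), oracle, tolerance = 1e-10)
  }
  expect_error(poissonLogLik(g, sm, c(-1, 0, 0, 0)), "non-negative")
  expect_error(poissonLogLik(g + 0.5, sm, rep(1, 4)), "integer")
})

test_that("EM update has the true uptake as a fixed point and stays nonnegative", {
  sm <- toySysmat(seed = 11)
  lamStar <- c(3, 1, 2, 4)
  g <- as.numeric(cbind(sm@HTh, sm@HRa) %*% lamStar) + sm@psi  # integer toy
  expect_equal(emUpdate(lamStar, g, sm), lamStar, tolerance = 1e-12)
  # zero stays zero; everything nonnegative
  lam0 <- c(0, 1, 2, 0)
  up <- emUpdate(lam0, g, sm)
  expect_identical(up[c(1, 4)], c(0, 0))
  expect_true(all(up >= 0))
})

test_that("scalar EM converges to the stationary point (g - psi)/H", {
  # duplicate columns split the flux equally from a symmetric init:
  # lambdaTh + lambdaRa converges to (g - psi)/H = (5 - 1)/2 = 2
  sm <- new("SystemMatrixSet", HTh = matrix(2), HRa = matrix(2), psi = 1,
            projDim = c(1L, 1L, 1L, 1L), voiNames = "V1",
            windows = energyWindows(100, 150), meta = list())
  est <- runMewPdq(5, sm, init = c(1, 1), maxIter = 500, traceEvery = 0,
                   logLikEvery = 0)
  expect_equal(est@lambdaTh + est@lambdaRa, c(V1 = 2), tolerance = 1e-6)
})

test_that("noiseless identifiability and init-invariance on full-rank toys", {
  for (seed in c(3, 17, 29)) {
    sm <- toySysmat(seed = seed, Ms = 8L, nW = 2L)
    set.seed(seed)
    lamStar <- sample(1:6, 4)
    g <- as.numeric(cbind(sm@HTh, sm@HRa) %*% lamStar) + sm@psi
    est <- runMewPdq(g, sm, maxIter = 20000L, tol = 1e-10)
    expect_equal(unname(uptakeVector(est)), lamStar, tolerance = 1e-3)
    # scaling the flat init by 10 does not move the converged estimate
    est10 <- runMewPdq(g, sm, init = rep(10 * mean(lamStar), 4),
                       maxIter = 20000L, tol = 1e-10)
    expect_equal(uptakeVector(est10), uptakeVector(est), tolerance = 1e-3)
  }
})

test_that("log-likelihood is non-decreasing across iterations on real data", {
  s <- tinySetup()
  g <- simulateProjections(s$sysmat, s$truth, seed = 31)
  est <- runMewPdq(g, s$sysmat, maxIter = 200L, logLikEvery = 1L)
  ll <- logLikTrace(est)$logLik
  expect_true(all(diff(ll) >= -1e-7 * pmax(abs(ll[-1]), 1)))
})

test_that("EM preserves total expected counts at convergence (flux identity)", {
  s <- tinySetup()
  g <- simulateProjections(s$sysmat, s$truth, seed = 33)
  est <- runMewPdq(g, s$sysmat, maxIter = 1000L, traceEvery = 0,
                   logLikEvery = 0)
  H <- systemMatrix(s$sysmat, "composite")
  fitted <- sum(H %*% uptakeVector(est)) + sum(strayMeans(s$sysmat))
  expect_equal(fitted, sum(counts(g)), tolerance = 1e-3)
})

test_that("crosstalk separation: data without Ra yields negligible Ra lesion", {
  s <- tinySetup()
  lamThOnly <- regionalUptakeValues(s$truth@lambdaTh, 0 * s$truth@lambdaRa,
                                    names = names(s$truth@lambdaTh))
  g <- simulateProjections(s$sysmat, lamThOnly, seed = 41)
  est <- runMewPdq(g, s$sysmat, maxIter = 1000L, traceEvery = 0,
                   logLikEvery = 0)
  sens <- colSums(systemMatrix(s$sysmat, "composite"))
  K <- nRegions(s$sysmat)
  les <- which(voiNames(s$sysmat) == "lesion")
  raCounts <- est@lambdaRa[les] * sens[K + les]
  thCounts <- est@lambdaTh[les] * sens[les]
  expect_lt(raCounts, 0.05 * thCounts)
})

test_that("estimator validates its inputs and records its protocol", {
  s <- tinySetup()
  g <- counts(simulateProjections(s$sysmat, s$truth, seed = 51))
  expect_error(runMewPdq(g - 1, s$sysmat), "non-negative")
  expect_error(runMewPdq(g + 0.25, s$sysmat), "integer")
  est <- runMewPdq(g, s$sysmat, maxIter = 120L, traceEvery = 50L,
                   logLikEvery = 0L)
  expect_identical(est@nIter, 120L)
  expect_identical(attr(estimateTrace(est), "iterations"), c(50, 100, 120))
  # early stopping truncates the records consistently
  est2 <- runMewPdq(g, s$sysmat, maxIter = 5000L, tol = 1e-3,
                    traceEvery = 50L, logLikEvery = 0L)
  expect_true(est2@converged)
  expect_lt(est2@nIter, 5000L)
})
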