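test_that("Fisher information matches closed form and a brute-force oracle", {
  # single bin, single active parameter: F = H^2 / (H lambda + psi) = 4/5
  sb <- singleBinSysmat(h = 2, psi = 1)
  fi <- fisherInformation(sb, c(2, 0))
  expect_equal(fi@matrix[1, 1], 4 / 5)
  # brute-force double loop over bins and parameter pairs
  sm <- toySysmat(seed = 6)
  lam <- c(1, 2, 3, 4)
  fi <- fisherInformation(sm, lam)
  H <- cbind(sm@HTh, sm@HRa)
  mu <- as.numeric(H %*% lam) + sm@psi
  oracle <- matrix(0, 4, 4)
  for (a in 1:4) for (b in 1:4)
    oracle[a, b] <- sum(H[, a] * H[, b] / mu)
  expect_equal(unname(fi@matrix), oracle, tolerance = 1e-10)
  # additivity over disjoint window subsets (exact)
  f1 <- fisherInformation(sm, lam, windowSubset = 1L)@matrix
  f2 <- fisherInformation(sm, lam, windowSubset = 2L)@matrix
  expect_equal(f1 + f2, fi@matrix, tolerance = 1e-12)
  # adding windows never decreases a diagonal entry
  expect_true(all(diag(fi@matrix) >= diag(f1) - 1e-12))
})

test_that("CRLB-derived NSD matches arithmetic and inversion oracles", {
  mk <- function(Fm, lam) new("FisherInfo", matrix = Fm, lambda = lam,
                              windowSubset = 1L)
  # 1-parameter arithmetic: CRLB = 5/4 at lambda = 2 -> sqrt(1.25)/2
  nsd <- crlbNsd(mk(diag(c(4 / 5, 4)), c(2, 1)))
  expect_equal(unname(nsd), c(sqrt(1.25) / 2, sqrt(0.25) / 1))
  # random SPD matrices against a numerical inverse oracle
  set.seed(14)
  for (r in 1:5) {
    A <- matrix(rnorm(16), 4)
    Fm <- crossprod(A) + diag(4) * 0.1
    lam <- runif(4, 0.5, 2)
    expect_equal(unname(crlbNsd(mk(Fm, lam))),
                 sqrt(diag(solve(Fm))) / lam, tolerance = 1e-8)
  }
  # singular matrix errors unless the pseudo-inverse fallback is enabled
  Fs <- matrix(1, 2, 2)
  expect_error(crlbNsd(mk(Fs, c(1, 1))), "singular")
  expect_warning(nsdp <- crlbNsd(mk(Fs, c(1, 1)), pseudoInverse = TRUE),
                 "pseudo-inverse")
  expect_true(all(is.finite(nsdp)))
})

test_that("window-subset study is monotone along nested subsets", {
  s <- tinySetup()
  tab <- windowSubsetStudy(s$sysmat, s$truth)
  wide <- matrix(tab$nsd, ncol = 4)  # parameters x subsets
  # information monotonicity: NSD non-increasing as windows accumulate
  expect_true(all(diff(t(wide)) <= 1e-9))
  # the single-window dual-isotope problem is the hardest
  expect_true(all(wide[, 1] >= wide[, 4]))
  expect_warning(windowSubsetStudy(s$sysmat, s$truth,
                                   subsets = list(1L, 3L)), "not nested")
})

test_that("merit figures follow their definitions and the Pythagorean identity", {
  truth <- regionalUptakeValues(2, 2, names = "V1")
  mkEst <- function(v) new("UptakeEstimate", lambdaTh = c(V1 = v),
                           lambdaRa = c(V1 = v), logLik = 0,
                           logLikIters = 1, trace = matrix(v),
                           traceIters = 1, nIter = 1L, converged = TRUE,
                           convergenceMetric = 0)
  # estimates equal to truth: all merit figures are zero
  m0 <- meritReport(list(mkEst(2), mkEst(2)), truth)
  expect_equal(m0$nb, c(0, 0))
  expect_equal(m0$nsd, c(0, 0))
  expect_equal(m0$nrmse, c(0, 0))
  # estimates {1, 3} about truth 2: NB = 0, NSD = 0.5, NRMSE = 0.5 (1/n sd)
  m <- meritReport(list(mkEst(1), mkEst(3)), truth)
  expect_equal(m$nb, c(0, 0))
  expect_equal(m$nsd, c(0.5, 0.5))
  expect_equal(m$nrmse, c(0.5, 0.5))
  # NRMSE^2 = NB^2 + NSD^2 on random fixtures
  set.seed(99)
  ests <- lapply(runif(20, 1, 3), mkEst)
  mr <- meritReport(ests, truth)
  expect_equal(mr$nrmse^2, mr$nb^2 + mr$nsd^2, tolerance = 1e-12)
  expect_error(meritReport(ests, regionalUptakeValues(0, 1, names = "V1")),
               "zero ground-truth")
})

test_that("ensemble metrics aggregate signed per-patient errors", {
  truths <- list(regionalUptakeValues(2, 2, names = "V1"),
                 regionalUptakeValues(4, 4, names = "V1"))
  ests <- list(list(lambdaTh = c(V1 = 2.2), lambdaRa = c(V1 = 1.8)),
               list(lambdaTh = c(V1 = 3.6), lambdaRa = c(V1 = 4.4)))
  em <- ensembleMerit(ests, truths)
  # Th errors: +0.1, -0.1 -> signed mean 0; Ra errors: -0.1, +0.1 -> 0
  expect_equal(em$ensembleNb, c(0, 0), tolerance = 1e-12)
  expect_equal(em$ensembleNrmse, c(0.1, 0.1), tolerance = 1e-12)
  expect_identical(em$nPatients, c(2L, 2L))
})
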