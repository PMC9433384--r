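test_that("noiseless growth-law data are recovered to numerical precision", {
  truth <- fullCoefficients(studyParams(), kChi = 4.8e4 * 1.5,
                            alphaPhi = 1.1e-3)
  tc <- curveCoefficients(truth)
  d <- generateGrowthLawDataset(truth, seq(1e-4, 6e-3, length.out = 10),
                                noiseSD = 0)
  f <- fitGrowthLaw(d)
  expect_lt(max(abs(curveCoefficients(f) - tc) / abs(tc)), 1e-6)
  expect_lt(fitRMSE(f), 1e-10)
  # point estimates sit inside their own intervals
  ci <- confint95(f)
  expect_true(all(ci[, 1] <= curveCoefficients(f) &
                    curveCoefficients(f) <= ci[, 2]))
})

test_that("constant-speed-line data give a c2 interval covering zero", {
  stm <- fullCoefficients(uniformParams(3), 4.8e4, 0)  # c2 = 0 truth
  d <- generateGrowthLawDataset(stm, seq(2e-4, 7e-3, length.out = 12),
                                noiseSD = 0.002, seed = 41)
  f <- fitGrowthLaw(d)
  ci <- confint95(f)
  expect_true(ci["c2", 1] <= 0 && 0 <= ci["c2", 2])
})

test_that("fitting rejects malformed datasets", {
  d <- data.frame(mu = c(0, 1e-3, 2e-3), phi_R = c(0.1, 0.2, 0.3))
  expect_error(fitGrowthLaw(d), "at least 4")
  d2 <- data.frame(mu = c(0, 1e-3, 2e-3, 3e-3), phi_R = c(0.1, 0.2, 0.3, 1.2))
  expect_error(fitGrowthLaw(d2), "strictly in")
})

test_that("coefficient inversion is the exact inverse of the forward map", {
  # closed-form specialization without degradation
  iv <- invertCoefficients(c1 = 2e-3, c2 = -1.2, c3 = 4e-2, alphaR = 0,
                           alphaPhi = 0, mR = 1.4e6)
  expect_equal(unname(iv["phi0"]), 2e-3 / 4e-2)
  expect_equal(unname(iv["kChi"]), 1.4e6 * 4e-2)
  expect_equal(unname(iv["kR"]), 1.4e6 * 4e-2 / 2.2)
  # round trip on the study parameter set
  tc <- curveCoefficients(fullCoefficients(studyParams(), 4.8e4, 1.1e-3))
  iv2 <- invertCoefficients(tc[1], tc[2], tc[3], 4.83e-4, 1.1e-3, 1.4e6)
  expect_equal(unname(iv2), c(0.08, 2.07e4, 4.8e4), tolerance = 1e-12)
  # property: inversion o forward = identity on random feasible inputs
  set.seed(55)
  for (r in 1:50) {
    kR <- runif(1, 1e4, 8e4); kChi <- runif(1, 1e4, 9e4)
    aR <- runif(1, 0, 1e-3); aP <- runif(1, 0, 3e-3)
    phi0 <- runif(1, 0, 0.3); mR <- runif(1, 5e5, 2e6)
    p <- ProteomeParams(k = c(kR, kChi), alpha = c(aR, aP), mR = mR,
                        phi0 = phi0)
    tc <- curveCoefficients(fullCoefficients(p, kChi, aP))
    iv <- invertCoefficients(tc[1], tc[2], tc[3], aR, aP, mR)
    expect_equal(unname(iv), c(phi0, kR, kChi), tolerance = 1e-10)
  }
  expect_error(invertCoefficients(1e-3, 1.2, 3e-2, 0, 0, 1e6), "c2")
})

test_that("confidence-box propagation brackets the point estimates and widens monotonically", {
  truth <- fullCoefficients(studyParams(), 7.2e4, 1.1e-3)
  d <- generateGrowthLawDataset(truth, seq(1e-4, 6e-3, length.out = 20),
                                noiseSD = 0.004, seed = 3)
  f <- fitGrowthLaw(d)
  b <- boundDerivedParams(f, alphaR = 4.83e-4, alphaPhi = 1.1e-3,
                          mR = 1.4e6)
  pt <- invertCoefficients(curveCoefficients(f)[1], curveCoefficients(f)[2],
                           curveCoefficients(f)[3], 4.83e-4, 1.1e-3, 1.4e6)
  expect_true(all(b[, 1] <= pt + 1e-12 & pt <= b[, 2] + 1e-12))
  # zero-width box degenerates to the point values
  f0 <- f
  f0@ci <- cbind(curveCoefficients(f), curveCoefficients(f))
  b0 <- boundDerivedParams(f0, 4.83e-4, 1.1e-3, mR = 1.4e6)
  expect_equal(b0[, 1], pt, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(b0[, 2], pt, tolerance = 1e-9, ignore_attr = TRUE)
  # widening the c2 interval can only widen the k_R interval
  fw <- f
  fw@ci["c2", ] <- f@ci["c2", ] + c(-0.3, 0.3)
  bw <- boundDerivedParams(fw, 4.83e-4, 1.1e-3, mR = 1.4e6)
  expect_lte(bw["kR", 1], b["kR", 1])
  expect_gte(bw["kR", 2], b["kR", 2])
  # grid+refinement result matches a dense Monte-Carlo min/max
  ci <- confint95(f)
  set.seed(9)
  P <- cbind(runif(1e6, ci[1, 1], ci[1, 2]), runif(1e6, ci[2, 1], ci[2, 2]),
             runif(1e6, ci[3, 1], ci[3, 2]))
  kChi <- 1.4e6 * (P[, 3] - 1.1e-3 + 4.83e-4 * (1 - P[, 2]))
  keep <- P[, 2] < 1 & kChi > 0
  mc <- rbind(range((P[keep, 1] - 1.1e-3) * 1.4e6 / kChi[keep]),
              range(kChi[keep] / (1 - P[keep, 2])),
              range(kChi[keep]))
  expect_lt(max(abs(b - mc) / abs(mc)), 0.005)
})

test_that("subsampled RMSE separates universal from non-universal pools", {
  # a pool on one exact curve has essentially zero fitting error (indices
  # targeted tightly so every environment shares the same curve)
  cfg <- ensembleConfig(nGenes = 150, nEnvironments = 25, seed = 61,
                        chiRRange = c(0.25, 0.45))
  tgt <- data.frame(IChiK = 0.4, IPhiAlpha = -0.1)
  one <- suppressWarnings(runEnsemble(cfg, mode = "full", targets = tgt,
                                      tol = 1e-7))
  sOne <- subsampleRmse(one, nPoints = 10, nReps = 30, seed = 1)
  expect_lt(sOne$median, 1e-8)
  expect_error(subsampleRmse(one, nPoints = 100, nReps = 5), "at least")
})

test_that("subsampled RMSE medians are stable under fewer replicates", {
  set.seed(71)
  # synthetic pool: two curves mixed, so RMSE is genuinely nonzero
  truthA <- fullCoefficients(studyParams(), 5e4, 1.1e-3)
  truthB <- fullCoefficients(studyParams(), 8e4, 1.6e-3)
  mu <- runif(120, 5e-4, 6e-3)
  phi <- ifelse(seq_along(mu) %% 2 == 0, phiRGrowthLaw(mu, truthA),
                phiRGrowthLaw(mu, truthB))
  pool <- data.frame(mu_per_min = mu, phi_R = phi)
  full <- subsampleRmse(pool, nPoints = 20, nReps = 1000, seed = 5)
  reduced <- subsampleRmse(pool, nPoints = 20, nReps = 200, seed = 6)
  expect_lt(abs(reduced$median - full$median) / full$median, 0.10)
})

test_that("condition-level phi_R predictions respond correctly to the indices", {
  pp <- ProteomeParams(k = c(2.07e4, rep(4.8e4, 3)),
                       alpha = c(4.83e-4, rep(1.1e-3, 3)), mR = 1.4e6,
                       phi0 = 0.08)
  # zero indices reduce to the arithmetic-mean coefficients
  cf <- fullCoefficients(pp, meanSpeed(pp), meanDegradation(pp))
  expect_equal(predictPhiRForConditions(pp, 3e-3, 0, 0),
               phiRGrowthLaw(3e-3, cf))
  # faster average translation needs fewer ribosomes
  expect_lt(predictPhiRForConditions(pp, 3e-3, 0.5, 0),
            predictPhiRForConditions(pp, 3e-3, 0, 0))
  # translation persists at zero growth: phi_R(0) > phi0 with degradation
  expect_gt(predictPhiRForConditions(pp, 0, 0, 0), 0.08)
  # shared phi0 override
  expect_equal(predictPhiRForConditions(pp, 0, 0, 0, phi0 = 0.048),
               phiRGrowthLaw(0, fullCoefficients(
                 ProteomeParams(k = translationSpeeds(pp),
                                alpha = degradationRates(pp), mR = 1.4e6,
                                phi0 = 0.048),
                 meanSpeed(pp), meanDegradation(pp))))
})

test_that("composition-prediction correlations rank the full model above its ablations", {
  cfg <- solvableConfig(200, seed = 81)
  p <- sampleProteome(cfg)
  e <- sampleEnvironment(cfg, p, seed = 82)
  st <- suppressWarnings(steadyState(p, e))
  meas <- massFractions(st)
  rho <- evaluatePhiPrediction(p, e, growthRate(st), meas)
  # self-generated measurements correlate perfectly with the full model
  expect_equal(unname(rho["full"]), 1, tolerance = 1e-9)
  # speed heterogeneity drives composition, so flattening k loses signal
  expect_gt(rho["full"], rho["k_homogeneous"])
  # shuffled measurements decorrelate
  set.seed(83)
  rhoShuf <- evaluatePhiPrediction(p, e, growthRate(st),
                                   c(meas[1], sample(meas[-1])))
  expect_lt(abs(rhoShuf["full"]), 0.2)
  expect_error(evaluatePhiPrediction(ProteomeParams(k = c(1, 1),
                                                    alpha = c(0, 0)),
                                     CellEnvironment(c(0.5, 0.5)), 1e-3,
                                     c(0.5, 0.5)),
               "at least 3")
})
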