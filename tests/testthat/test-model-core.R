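test_that("correlation index decouples for constant weights or values and matches direct arithmetic", {
  # uniform weights decouple
  expect_equal(correlationIndex(rep(1 / 4, 4), c(1, 7, 2, 9)), 0)
  # constant values decouple
  expect_equal(correlationIndex(c(0.7, 0.2, 0.1), rep(3, 3)), 0)
  # direct arithmetic oracle: mean(wx) = 3.4/3, mean(w)*mean(x) = 4/3
  expect_equal(correlationIndex(c(0.5, 0.3, 0.2), c(2, 4, 6)),
               (3.4 / 3 - 4 / 3) / (4 / 3))
  expect_equal(correlationIndex(c(0.5, 0.3, 0.2), c(2, 4, 6)), -0.15)
})

test_that("correlation index rejects invalid input", {
  expect_error(correlationIndex(c(0.5, 0.5), c(1, 2, 3)), "dimension")
  expect_error(correlationIndex(c(0.5, 0.5), c(0, 0)), "undefined")
  expect_error(correlationIndex(c(0.9, 0.3), c(1, 2)), "sum to 1")
})

test_that("weighted speed and degradation satisfy the <x>_w = <x>(1 + I) identity", {
  # uniform chi-tilde gives the arithmetic mean
  pp <- ProteomeParams(k = c(2e4, 2, 4, 6), alpha = c(0, 1, 2, 3) * 1e-3)
  expect_equal(weightedSpeed(pp, uniformEnv(4)), 4)
  # homogeneous non-ribosomal speeds give that speed back
  expect_equal(weightedSpeed(uniformParams(4), uniformEnv(4)), 4.8e4)
  # 3-protein example ties to the correlation index: 3.4 = 4 * (1 - 0.15)
  env <- CellEnvironment(c(0.2, 0.8 * c(0.5, 0.3, 0.2)))
  expect_equal(weightedSpeed(pp, env), 3.4)
  expect_equal(weightedSpeed(pp, env),
               mean(c(2, 4, 6)) * (1 + correlationIndex(c(0.5, 0.3, 0.2),
                                                        c(2, 4, 6))))
  # same identity for degradation, property-style over random draws
  set.seed(1)
  for (r in 1:20) {
    n <- sample(3:30, 1)
    k <- c(2e4, runif(n - 1, 1e4, 9e4))
    al <- c(5e-4, runif(n - 1, 0, 5e-3))
    p <- ProteomeParams(k = k, alpha = al)
    w <- runif(n - 1); w <- w / sum(w)
    phi <- c(0.3, 0.7 * w)
    expect_equal(weightedDegradation(p, phi),
                 mean(al[-1]) * (1 + correlationIndex(w, al[-1])))
    ct <- runif(n - 1); ct <- ct / sum(ct)
    e <- CellEnvironment(c(0.25, 0.75 * ct))
    expect_equal(weightedSpeed(p, e),
                 mean(k[-1]) * (1 + correlationIndex(ct, k[-1])))
  }
  expect_error(weightedSpeed(uniformParams(3),
                             CellEnvironment(c(1, 0, 0))), "degenerate")
})

test_that("Hill coefficients match hand arithmetic and vanish at equal speeds", {
  pp <- studyParams()
  # k_R = <k>_chi collapses to the constant-speed line (a = 0)
  expect_equal(unname(hillCoefficients(pp, 2.07e4)["a"]), 0)
  # hand oracle: a = -27300 / 22884, b = 20700*48000 / (1.4e6 * 22884)
  hc <- hillCoefficients(pp, 4.80e4)
  expect_equal(unname(hc["a"]), -27300 / 22884, tolerance = 1e-12)
  expect_equal(unname(hc["a"]), -1.19298, tolerance = 1e-5)
  expect_equal(unname(hc["b"]), 20700 * 48000 / (1.4e6 * 22884),
               tolerance = 1e-12)
  expect_equal(unname(hc["b"]), 0.031013, tolerance = 1e-4)
})

test_that("linear coefficients match hand arithmetic and vanish for uniform degradation", {
  # no degradation at all: the constant-speed line
  p0 <- uniformParams(3)
  expect_equal(unname(linearCoefficients(p0, 0)), c(0, 0))
  # uniform degradation: c = alpha, d = 0
  pu <- ProteomeParams(k = rep(4.8e4, 3), alpha = rep(2e-3, 3))
  expect_equal(unname(linearCoefficients(pu, 2e-3)), c(2e-3, 0))
  # hand oracle: c = 1.1e-3*0.92 + 4.83e-4*0.08, d = 1.1e-3 - 4.83e-4
  lc <- linearCoefficients(studyParams(), 1.10e-3)
  expect_equal(unname(lc["c"]), 1.10e-3 * 0.92 + 4.83e-4 * 0.08,
               tolerance = 1e-12)
  expect_equal(unname(lc["c"]), 1.0506e-3, tolerance = 1e-4)
  expect_equal(unname(lc["d"]), 6.17e-4, tolerance = 1e-12)
})

test_that("full coefficients reduce to the Hill and constant-speed forms", {
  pp <- studyParams()
  cf <- fullCoefficients(pp, 4.80e4, 1.10e-3)
  expect_equal(unname(curveCoefficients(cf)["c2"]), 1 - 48000 / 20700,
               tolerance = 1e-12)
  expect_equal(unname(curveCoefficients(cf)["c2"]), -1.31884,
               tolerance = 1e-5)
  # with alpha = 0 the rational form is algebraically the Hill form
  p0 <- ProteomeParams(k = c(2.07e4, 4.8e4), alpha = c(0, 0), mR = 1.4e6,
                       phi0 = 0.08)
  cf0 <- fullCoefficients(p0, 5.5e4, 0)
  hc <- hillCoefficients(p0, 5.5e4)
  set.seed(2)
  mu <- runif(100, 0, 8e-3)
  expect_equal(phiRGrowthLaw(mu, cf0),
               mu / (hc["a"] * mu + hc["b"]) + 0.08,
               tolerance = 1e-12, ignore_attr = TRUE)
  # homogeneous speed and no degradation: the constant-speed line
  pSTM <- uniformParams(3)
  cfS <- fullCoefficients(pSTM, 4.8e4, 0)
  expect_equal(phiRGrowthLaw(mu, cfS), 1.4e6 * mu / 4.8e4 + 0.08,
               tolerance = 1e-12)
})

test_that("growth-law curve evaluation handles the intercept and the pole", {
  cf <- GrowthLawCoefficients(2e-3, -1.3, 3.5e-2)
  expect_equal(phiRGrowthLaw(0, cf), 2e-3 / 3.5e-2)
  expect_error(phiRGrowthLaw(0.1, cf), "pole")
})

test_that("curve shape flags follow the discriminant", {
  # constant-speed line: increasing, c2 = 0 so neither convex nor concave
  sh <- curveShape(fullCoefficients(uniformParams(3), 4.8e4, 0))
  expect_true(sh$increasing)
  expect_false(sh$convex)
  # study parameters (k_R < <k>_chi, alpha_R < <alpha>_phi): increasing and convex
  sh2 <- curveShape(fullCoefficients(studyParams(), 4.8e4, 1.1e-3))
  expect_true(sh2$increasing)
  expect_true(sh2$convex)
  # constructed counter-case c3 < c1 c2
  sh3 <- curveShape(GrowthLawCoefficients(1, 2, 1))
  expect_false(sh3$increasing)
})

test_that("solver recovers the homogeneous closed form phi = chi, mu = k(chi_R - phi0)/m_R", {
  pp <- uniformParams(5)
  env <- uniformEnv(5, chiR = 0.3)
  st <- steadyState(pp, env)
  expect_equal(growthRate(st), 4.8e4 * (0.3 - 0.08) / 1.4e6,
               tolerance = 1e-12)
  expect_equal(growthRate(st), 7.5429e-3, tolerance = 1e-4)
  expect_equal(phiR(st), 0.3, tolerance = 1e-12)
  expect_equal(massFractions(st), allocations(env), tolerance = 1e-12)
})

test_that("solver satisfies its exactness identities on random heterogeneous instances", {
  for (s in 1:10) {
    cfg <- solvableConfig(150, seed = 300 + s)
    p <- sampleProteome(cfg)
    e <- sampleEnvironment(cfg, p, seed = 400 + s)
    st <- suppressWarnings(steadyState(p, e))
    # solved phi_R equals the closed-form curve at realized weighted means
    cf <- fullCoefficients(p, weightedSpeedValue(st),
                           weightedDegradationValue(st))
    expect_lt(abs(phiR(st) - phiRGrowthLaw(growthRate(st), cf)), 1e-10)
    # normalization residual of the self-consistency condition
    resid <- 1 - (phiR(st) - inactiveFraction(p)) / ribosomeMass(p) *
      sum(translationSpeeds(p) * allocations(e) /
            (growthRate(st) + degradationRates(p)))
    expect_lt(abs(resid), 1e-9)
    # every per-protein growth rate equals mu
    expect_lt(max(abs(st@muPerProtein - growthRate(st))) /
                abs(growthRate(st)), 1e-9)
    expect_lt(abs(sum(massFractions(st)) - 1), 1e-10)
    expect_gt(phiR(st), inactiveFraction(p))
  }
})

test_that("solver rejects degenerate allocations and reports multiple roots on request", {
  pp <- uniformParams(3)
  expect_error(steadyState(pp, CellEnvironment(c(0, 0.5, 0.5))),
               "degenerate")
  expect_error(steadyState(pp, CellEnvironment(c(1, 0, 0))), "degenerate")
  # heterogeneous degradation creates a subdominant root; the strict policy
  # must report all roots, the default must match the dynamics (tested with
  # the ODE below)
  cfg <- solvableConfig(50, seed = 42)
  p <- sampleProteome(cfg)
  e <- sampleEnvironment(cfg, p, seed = 43)
  expect_error(steadyState(p, e, multiRoot = "error"),
               "multiple roots.*mu", perl = TRUE)
  expect_s4_class(steadyState(p, e), "SteadyState")
})

test_that("predicted composition follows speed/degradation intuition and manual arithmetic", {
  # homogeneous speeds and degradation: phi = chi
  pp <- ProteomeParams(k = rep(3e4, 4), alpha = rep(1e-3, 4))
  env <- CellEnvironment(c(0.4, 0.3, 0.2, 0.1))
  expect_equal(predictPhi(pp, env, 5e-3), allocations(env),
               tolerance = 1e-14)
  # equal allocation, speed ratio 2:1, no degradation: mass ratio 2:1
  p2 <- ProteomeParams(k = c(2, 1), alpha = c(0, 0))
  ph <- predictPhi(p2, CellEnvironment(c(0.5, 0.5)), 1e-3)
  expect_equal(ph[1] / ph[2], 2)
  # spreadsheet-style manual evaluation of a 3-protein instance
  p3 <- ProteomeParams(k = c(2e4, 4e4, 6e4), alpha = c(1e-4, 2e-3, 5e-4))
  e3 <- CellEnvironment(c(0.3, 0.5, 0.2))
  terms <- c(2e4 * 0.3 / (5e-3 + 1e-4), 4e4 * 0.5 / (5e-3 + 2e-3),
             6e4 * 0.2 / (5e-3 + 5e-4))
  expect_equal(predictPhi(p3, e3, 5e-3), terms / sum(terms),
               tolerance = 1e-14)
  # monotonicity: raising k_i raises phi_i, raising alpha_i lowers it
  p3b <- ProteomeParams(k = c(2e4, 4e4 * 1.2, 6e4), alpha = degradationRates(p3))
  expect_gt(predictPhi(p3b, e3, 5e-3)[2], predictPhi(p3, e3, 5e-3)[2])
  p3c <- ProteomeParams(k = translationSpeeds(p3),
                        alpha = c(1e-4, 4e-3, 5e-4))
  expect_lt(predictPhi(p3c, e3, 5e-3)[2], predictPhi(p3, e3, 5e-3)[2])
  expect_error(predictPhi(p3, e3, -1e-3), "domain")
})

test_that("mass dynamics hold the steady composition fixed and converge to it", {
  # starting at the steady composition, fractions stay put over ~10 doublings
  cfg <- solvableConfig(40, seed = 7)
  p <- sampleProteome(cfg)
  e <- sampleEnvironment(cfg, p, seed = 8)
  st <- suppressWarnings(steadyState(p, e))
  tEnd <- 10 * log(2) / growthRate(st)
  out <- integrateDynamics(p, e, massFractions(st), seq(0, tEnd, length.out = 20))
  phiEnd <- out[20, -1] / sum(out[20, -1])
  expect_lt(max(abs(phiEnd - massFractions(st))), 1e-8)
  # homogeneous-speed, degradation-free case converges to phi = chi from
  # any positive start
  pu <- uniformParams(6)
  eu <- CellEnvironment(c(0.35, 0.05, 0.1, 0.15, 0.2, 0.15))
  set.seed(3)
  # positive start with more active than inactive ribosomes (a ribosomal
  # deficit under zero degradation collapses instead of growing)
  M0 <- runif(6, 0.2, 2)
  M0[1] <- max(M0[1], 0.15 * sum(M0))
  stU <- steadyState(pu, eu)
  outU <- integrateDynamics(pu, eu, M0,
                            seq(0, 30 / growthRate(stU), length.out = 50))
  phiU <- outU[50, -1] / sum(outU[50, -1])
  expect_equal(phiU, allocations(eu), tolerance = 1e-6)
  # log-slope of total mass over the last stretch equals the solved mu
  sl <- stats::coef(stats::lm(log(rowSums(outU[40:50, -1])) ~
                                outU[40:50, 1]))[[2]]
  expect_equal(sl, growthRate(stU), tolerance = 1e-9)
})
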