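#' Generate a synthetic multi-condition study with known ground truth
#'
#' Emulates the processed outputs of a ribosome-profiling + proteomics
#' study: one fixed proteome; per condition an environment targeted at
#' scheduled correlation indices, solved to steady state; and per-condition
#' gene tables (allocation count fractions, mass fractions, speeds,
#' degradation rates, lengths, amino-acid masses) plus OD600 growth curves
#' whose exponential rate is the condition's solved growth rate.
#' Measurement noise is multiplicative unit-mean lognormal per table;
#' fraction columns are renormalized after noise.  With all noise CVs zero
#' the emitted tables reproduce the ground truth exactly.
#'
#' @param nGenes number of genes (default 200).
#' @param schedule data.frame of per-condition targets with columns
#'   \code{IChiK} and \code{IPhiAlpha} (targets > -1).
#' @param noiseCV named list of measurement CVs: \code{chi}, \code{phi},
#'   \code{k}, \code{alpha} (default all 0).
#' @param seed master seed.
#' @param config optional [EnsembleConfig-class] overriding the default
#'   study conditions (its \code{nGenes}/\code{seed} are replaced by the
#'   arguments above).
#' @param tol index-targeting tolerance.
#' @return a [SyntheticStudy-class].
#' @examples
#' st <- generateStudy(nGenes = 50,
#'                     schedule = data.frame(IChiK = c(0, 0.5),
#'                                           IPhiAlpha = c(0, 0)),
#'                     seed = 1)
#' studyTables(st)[[1]][1:3, ]
#' @export
generateStudy <- function(nGenes = 200L,
                          schedule = data.frame(IChiK = c(0, 0.25, 0.5, 0.75),
                                                IPhiAlpha = rep(0, 4)),
                          noiseCV = list(chi = 0, phi = 0, k = 0, alpha = 0),
                          seed = 1L, config = NULL, tol = 1e-3) {
  schedule <- as.data.frame(schedule)
  stopifnot(all(c("IChiK", "IPhiAlpha") %in% names(schedule)))
  if (any(schedule$IChiK <= -1) || any(schedule$IPhiAlpha <= -1))
    stop("index targets must be > -1")
  noise <- utils::modifyList(list(chi = 0, phi = 0, k = 0, alpha = 0),
                             as.list(noiseCV))
  if (is.null(config)) config <- ensembleConfig()
  config <- ensembleConfig(nGenes = nGenes, meanK = config@meanK,
                           kR = config@kR, meanAlpha = config@meanAlpha,
                           alphaR = config@alphaR, cvK = config@cvK,
                           cvAlpha = config@cvAlpha, cvChi = config@cvChi,
                           phi0 = config@phi0, mR = config@mR,
                           chiRRange = config@chiRRange,
                           nEnvironments = nrow(schedule), seed = seed)
  params <- sampleProteome(config)
  nC <- nrow(schedule)
  envs <- states <- tables <- odCurves <- vector("list", nC)
  geneIds <- c("RIBOSOME", sprintf("GENE%04d", seq_len(nGenes - 1L)))
  set.seed(.subSeed(seed, 7))
  lp <- .lnormPars(450, 0.5)
  lengths <- round(stats::rlnorm(nGenes, lp[1], lp[2]))
  lengths[lengths < 30] <- 30
  aa <- rep(110, nGenes)          # mean amino-acid mass, Da

  renorm <- function(x) x / sum(x)
  for (j in seq_len(nC)) {
    envs[[j]] <- sampleEnvironmentTargeted(
      config, params, targetIChiK = schedule$IChiK[j],
      targetIPhiAlpha = schedule$IPhiAlpha[j], tol = tol,
      seed = .subSeed(seed, 1000 + j))
    states[[j]] <- steadyState(params, envs[[j]])

    noiseSeed <- .subSeed(seed, 500000 + j)
    chi <- allocations(envs[[j]])
    phi <- massFractions(states[[j]])
    k <- translationSpeeds(params)
    alpha <- degradationRates(params)
    if (noise$chi > 0)
      chi <- renorm(perturbWithNoise(chi, noise$chi, seed = noiseSeed))
    if (noise$phi > 0)
      phi <- renorm(perturbWithNoise(phi, noise$phi,
                                     seed = .subSeed(noiseSeed, 1)))
    if (noise$k > 0)
      k <- perturbWithNoise(k, noise$k, seed = .subSeed(noiseSeed, 2))
    if (noise$alpha > 0)
      alpha <- perturbWithNoise(alpha, noise$alpha,
                                seed = .subSeed(noiseSeed, 3))
    tables[[j]] <- data.frame(gene_id = geneIds, chi = chi, k = k,
                              v = k / aa, a = aa, alpha = alpha, phi = phi,
                              length = lengths,
                              is_ribosomal = c(TRUE,
                                               rep(FALSE, nGenes - 1L)))
    odCurves[[j]] <- generateODCurve(mu = growthRate(states[[j]]),
                                     seed = .subSeed(seed, 900000 + j))
  }
  new("SyntheticStudy", proteome = params, environments = envs,
      states = states, tables = tables, odCurves = odCurves,
      schedule = schedule, noiseCV = noise, seed = as.integer(seed))
}

#' Generate a growth-law dataset from known coefficients
#'
#' Evaluates the growth-law curve on a grid of growth rates and adds
#' Gaussian measurement noise to the ribosomal fractions (truncated to stay
#' inside (0, 1)); the test feed for [fitGrowthLaw()].
#'
#' @param truth a [GrowthLawCoefficients-class].
#' @param muGrid growth rates, 1/min, inside the curve's domain.
#' @param noiseSD standard deviation of the additive noise on phi_R.
#' @param seed RNG seed.
#' @return data.frame with columns \code{mu}, \code{phi_R}.
#' @export
generateGrowthLawDataset <- function(truth, muGrid, noiseSD = 0, seed = 1L) {
  stopifnot(is(truth, "GrowthLawCoefficients"))
  phi <- phiRGrowthLaw(muGrid, truth)
  if (noiseSD > 0) {
    set.seed(seed)
    phi <- phi + stats::rnorm(length(muGrid), 0, noiseSD)
  }
  phi <- pmin(pmax(phi, 1e-6), 1 - 1e-6)
  data.frame(mu = muGrid, phi_R = phi)
}

#' Generate a synthetic OD600 growth curve
#'
#' A lag phase at the inoculation density, then logistic growth whose
#' early-exponential log-slope equals \code{mu}, saturating at
#' \code{saturationOD}; optional multiplicative unit-mean lognormal
#' measurement noise.  The default inoculum is small relative to the
#' carrying capacity so that the exponential window is long and nearly
#' unsaturated.
#'
#' @param mu exponential growth rate, 1/min (> 0).
#' @param od0 inoculation OD (default 0.005).
#' @param lagMin lag duration, min (default 60).
#' @param saturationOD carrying capacity (default 2.5).
#' @param noiseCV measurement CV (default 0).
#' @param dtMin sampling interval, min (default 5).
#' @param durationMin total duration, min; default long enough to reach
#'   90\% of saturation.
#' @param seed RNG seed for the noise.
#' @return data.frame with columns \code{time_min}, \code{od}.
#' @export
generateODCurve <- function(mu, od0 = 0.005, lagMin = 60,
                            saturationOD = 2.5, noiseCV = 0, dtMin = 5,
                            durationMin = NULL, seed = 1L) {
  if (mu <= 0) stop("mu must be positive")
  if (is.null(durationMin))
    durationMin <- lagMin + log(9 * (saturationOD - od0) / od0) / mu
  t <- seq(0, durationMin, by = dtMin)
  te <- pmax(t - lagMin, 0)
  if (is.finite(saturationOD)) {
    K <- saturationOD
    od <- K * od0 * exp(mu * te) / (K + od0 * (exp(mu * te) - 1))
  } else {
    od <- od0 * exp(mu * te)
  }
  if (noiseCV > 0) {
    set.seed(seed)
    sdlog <- sqrt(log1p(noiseCV^2))
    od <- od * stats::rlnorm(length(od), -sdlog^2 / 2, sdlog)
  }
  data.frame(time_min = t, od = od)
}
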