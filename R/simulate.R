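## lognormal parameterized by (mean, CV) via moment matching
.lnormPars <- function(mean, cv) {
  sdlog <- sqrt(log1p(cv^2))
  c(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

## documented substreams of the master seed: offset 1 = proteome,
## 1000 + i = environment i, 500000 + i = noise draw i
.subSeed <- function(seed, offset) {
  (as.numeric(seed) * 1009 + as.numeric(offset)) %% 2147483629
}

#' Sample a random proteome
#'
#' Non-ribosomal translation speeds and degradation rates are drawn from
#' lognormal distributions moment-matched to the configured (mean, CV);
#' entry 1 is set to the ribosomal values exactly.  A zero configured mean
#' degradation rate yields a degradation-free proteome.
#'
#' @param config an [EnsembleConfig-class].
#' @param seed optional override of the proteome substream seed.
#' @return a [ProteomeParams-class].
#' @export
sampleProteome <- function(config, seed = .subSeed(config@seed, 1)) {
  set.seed(seed)
  n <- config@nGenes
  pk <- .lnormPars(config@meanK, config@cvK)
  k <- c(config@kR, stats::rlnorm(n - 1L, pk[1], pk[2]))
  if (config@meanAlpha > 0) {
    pa <- .lnormPars(config@meanAlpha, config@cvAlpha)
    alpha <- c(config@alphaR, stats::rlnorm(n - 1L, pa[1], pa[2]))
  } else {
    alpha <- rep(0, n)
  }
  ProteomeParams(k = k, alpha = alpha, mR = config@mR, phi0 = config@phi0)
}

#' Sample a random environment
#'
#' The ribosomal allocation \eqn{\chi_R} is uniform on the configured range;
#' renormalized non-ribosomal allocations \eqn{\tilde\chi} are lognormal
#' draws normalized to sum to 1.
#'
#' @param config an [EnsembleConfig-class].
#' @param params the [ProteomeParams-class] the environment applies to.
#' @param seed optional override of the environment substream seed.
#' @return a [CellEnvironment-class].
#' @export
sampleEnvironment <- function(config, params,
                              seed = .subSeed(config@seed, 1000)) {
  set.seed(seed)
  n <- nGenes(params)
  cR <- stats::runif(1, config@chiRRange[1], config@chiRRange[2])
  pc <- .lnormPars(1, config@cvChi)
  raw <- stats::rlnorm(n - 1L, pc[1], pc[2])
  CellEnvironment(c(cR, (1 - cR) * raw / sum(raw)))
}

## chi-tilde from the Gaussian-copula latent construction: couple the
## allocation ranks to the speed ranks (weight rhoK) and degradation-rate
## ranks (weight rhoA); the residual variance keeps the marginal lognormal.
.copulaChiTilde <- function(zK, zA, eps, rhoK, rhoA, meanlog, sdlog) {
  res <- 1 - rhoK^2 - rhoA^2
  lat <- rhoK * zK + rhoA * zA + sqrt(max(res, 0)) * eps
  u <- pmin(pmax(stats::pnorm(lat), 1e-15), 1 - 1e-15)
  raw <- stats::qlnorm(u, meanlog, sdlog)
  raw / sum(raw)
}

#' Sample an environment with preselected correlation indices
#'
#' Builds allocations whose realized index against the translation speeds
#' (and, optionally, whose steady-state index against the degradation
#' rates) hits the given target(s) to within \code{tol}.  Allocations are
#' coupled to the speed/degradation ranks through a Gaussian-copula latent
#' variable; the coupling weight(s) are root-found for each residual draw,
#' and fresh draws are attempted (up to \code{maxAttempts} candidate
#' evaluations) when the target is outside the reachable range.  A target
#' beyond what the speed spread supports raises an infeasibility error.
#'
#' @param config an [EnsembleConfig-class].
#' @param params the shared [ProteomeParams-class].
#' @param targetIChiK target allocation-speed index, or NULL to leave it
#'   free.
#' @param targetIPhiAlpha target mass-degradation index (requires a
#'   steady-state solve per candidate), or NULL to leave it free.
#' @param tol absolute tolerance on each realized index (default 1e-3).
#' @param maxAttempts cap on candidate-environment evaluations (default
#'   1e4).
#' @param seed optional override of the environment substream seed.
#' @return a [CellEnvironment-class] whose realized indices meet the
#'   targets.
#' @export
sampleEnvironmentTargeted <- function(config, params, targetIChiK = NULL,
                                      targetIPhiAlpha = NULL, tol = 1e-3,
                                      maxAttempts = 1e4,
                                      seed = .subSeed(config@seed, 1000)) {
  if (is.null(targetIChiK) && is.null(targetIPhiAlpha))
    stop("at least one index target is required")
  for (t in c(targetIChiK, targetIPhiAlpha))
    if (t <= -1) stop("index targets must be > -1")
  set.seed(seed)
  n <- nGenes(params)
  kNR <- translationSpeeds(params)[-1]
  aNR <- degradationRates(params)[-1]
  zK <- stats::qnorm(rank(kNR, ties.method = "first") / (n))
  zA <- stats::qnorm(rank(aNR, ties.method = "first") / (n))
  pc <- .lnormPars(1, config@cvChi)
  evals <- 0L

  makeEnv <- function(cR, ct) CellEnvironment(c(cR, (1 - cR) * ct))

  repeat {
    cR <- stats::runif(1, config@chiRRange[1], config@chiRRange[2])
    eps <- stats::rnorm(n - 1L)

    if (is.null(targetIPhiAlpha)) {
      ## deterministic 1-D problem in the speed-coupling weight
      f <- function(rho) {
        ct <- .copulaChiTilde(zK, zA, eps, rho, 0, pc[1], pc[2])
        correlationIndex(ct, kNR) - targetIChiK
      }
      lo <- f(-0.999); hi <- f(0.999)
      evals <- evals + 2L
      if (is.finite(lo) && is.finite(hi) && lo * hi <= 0) {
        r <- stats::uniroot(f, c(-0.999, 0.999), tol = 1e-12)
        evals <- evals + 60L
        ct <- .copulaChiTilde(zK, zA, eps, r$root, 0, pc[1], pc[2])
        if (abs(correlationIndex(ct, kNR) - targetIChiK) <= tol)
          return(makeEnv(cR, ct))
      }
    } else if (is.null(targetIChiK)) {
      ## 1-D problem in the degradation-coupling weight; the realized index
      ## lives on the solved steady state
      f <- function(rho) {
        ct <- .copulaChiTilde(zK, zA, eps, 0, rho, pc[1], pc[2])
        st <- steadyState(params, makeEnv(cR, ct))
        massDegradationIndex(st) - targetIPhiAlpha
      }
      lo <- try(f(-0.999), silent = TRUE); hi <- try(f(0.999), silent = TRUE)
      evals <- evals + 2L
      if (is.numeric(lo) && is.numeric(hi) && lo * hi <= 0) {
        r <- stats::uniroot(f, c(-0.999, 0.999), tol = 1e-9)
        evals <- evals + 40L
        ct <- .copulaChiTilde(zK, zA, eps, 0, r$root, pc[1], pc[2])
        st <- steadyState(params, makeEnv(cR, ct))
        if (abs(massDegradationIndex(st) - targetIPhiAlpha) <= tol)
          return(makeEnv(cR, ct))
      }
    } else {
      ## 2-D problem: damped Newton on both coupling weights (mapped into
      ## the unit disc), starting from the 1-D speed-only solution
      chiOf <- function(p) {
        s <- sqrt(1 + sum(p^2))
        .copulaChiTilde(zK, zA, eps, p[1] / s, p[2] / s, pc[1], pc[2])
      }
      resid <- function(p) {
        ct <- chiOf(p)
        d1 <- correlationIndex(ct, kNR) - targetIChiK
        st <- try(suppressWarnings(steadyState(params, makeEnv(cR, ct))),
                  silent = TRUE)
        if (inherits(st, "try-error")) return(c(NA_real_, NA_real_))
        c(d1, massDegradationIndex(st) - targetIPhiAlpha)
      }
      f1 <- function(rho) {
        ct <- .copulaChiTilde(zK, zA, eps, rho, 0, pc[1], pc[2])
        correlationIndex(ct, kNR) - targetIChiK
      }
      lo <- f1(-0.999); hi <- f1(0.999)
      evals <- evals + 2L
      if (is.finite(lo) && is.finite(hi) && lo * hi <= 0) {
        rho0 <- stats::uniroot(f1, c(-0.999, 0.999), tol = 1e-6)$root
        evals <- evals + 30L
        p <- c(rho0 / sqrt(max(1 - rho0^2, 1e-6)), 0)
        d <- resid(p)
        for (iter in 1:30) {
          evals <- evals + 3L
          if (anyNA(d)) break
          if (max(abs(d)) <= tol * 0.3) return(makeEnv(cR, chiOf(p)))
          h <- 1e-4
          dA <- resid(p + c(h, 0)); dB <- resid(p + c(0, h))
          if (anyNA(dA) || anyNA(dB)) break
          J <- cbind((dA - d) / h, (dB - d) / h)
          step <- try(solve(J, -d), silent = TRUE)
          if (inherits(step, "try-error")) break
          nrm <- sqrt(sum(step^2))
          if (nrm > 1) step <- step / nrm        # damp long steps
          pNew <- p + step
          dNew <- resid(pNew)
          if (!anyNA(dNew) && sum(dNew^2) < sum(d^2) * 0.999) {
            p <- pNew; d <- dNew
          } else {                                # halve until improving
            ok <- FALSE
            for (half in 1:6) {
              step <- step / 2
              dNew <- resid(p + step)
              evals <- evals + 1L
              if (!anyNA(dNew) && sum(dNew^2) < sum(d^2)) {
                p <- p + step; d <- dNew; ok <- TRUE; break
              }
            }
            if (!ok) break
          }
        }
        if (!anyNA(d) && max(abs(d)) <= tol)
          return(makeEnv(cR, chiOf(p)))
      }
    }
    if (evals >= maxAttempts)
      stop(sprintf(
        "targeting infeasible: could not reach index target(s) within %d attempts (spread of k/alpha may not support the target)",
        as.integer(maxAttempts)))
  }
}

#' Apply multiplicative measurement noise
#'
#' Multiplies each entry by a unit-mean lognormal factor with the given CV.
#' For a [CellEnvironment-class] the allocations are renormalized to sum to
#' 1 afterwards; for a [ProteomeParams-class] the translation speeds are
#' perturbed.  A zero CV is the identity.
#'
#' @param x a [ProteomeParams-class] or [CellEnvironment-class].
#' @param noiseCV coefficient of variation of the noise (>= 0).
#' @param seed optional seed for the noise substream.
#' @return a perturbed copy of \code{x}.
#' @export
perturbWithNoise <- function(x, noiseCV, seed = NULL) {
  if (noiseCV < 0) stop("noiseCV must be >= 0")
  if (noiseCV == 0) return(x)
  if (!is.null(seed)) set.seed(seed)
  sdlog <- sqrt(log1p(noiseCV^2))
  if (is(x, "ProteomeParams")) {
    fac <- stats::rlnorm(nGenes(x), -sdlog^2 / 2, sdlog)
    ProteomeParams(k = translationSpeeds(x) * fac,
                   alpha = degradationRates(x), mR = ribosomeMass(x),
                   phi0 = inactiveFraction(x))
  } else if (is(x, "CellEnvironment")) {
    fac <- stats::rlnorm(length(allocations(x)), -sdlog^2 / 2, sdlog)
    CellEnvironment(allocations(x) * fac, normalize = TRUE)
  } else if (is.numeric(x)) {
    x * stats::rlnorm(length(x), -sdlog^2 / 2, sdlog)
  } else stop("unsupported type for perturbWithNoise")
}

#' Draw a per-environment schedule of index targets
#'
#' Emulates studies in which each environment's correlation indices are
#' drawn from two-dimensional Gaussian distributions; targets are resampled
#' until they fall inside the feasible bounds.
#'
#' @param n number of environments.
#' @param meanIChiK,sdIChiK mean and sd of the allocation-speed index draw.
#' @param meanIPhiAlpha,sdIPhiAlpha mean and sd of the mass-degradation
#'   index draw.
#' @param boundsIChiK,boundsIPhiAlpha feasible intervals for resampling.
#' @param seed seed of the draw.
#' @return data.frame with columns \code{IChiK}, \code{IPhiAlpha}.
#' @export
sampleIndexSchedule <- function(n, meanIChiK = 0.5, sdIChiK = 0.5,
                                meanIPhiAlpha = 0, sdIPhiAlpha = 0.5,
                                boundsIChiK = c(-0.4, 0.8),
                                boundsIPhiAlpha = c(-0.5, 0.3),
                                seed = 1L) {
  set.seed(seed)
  drawTrunc <- function(n, m, s, b) {
    x <- stats::rnorm(n, m, s)
    bad <- x < b[1] | x > b[2]
    while (any(bad)) {
      x[bad] <- stats::rnorm(sum(bad), m, s)
      bad <- x < b[1] | x > b[2]
    }
    x
  }
  data.frame(IChiK = drawTrunc(n, meanIChiK, sdIChiK, boundsIChiK),
             IPhiAlpha = drawTrunc(n, meanIPhiAlpha, sdIPhiAlpha,
                                   boundsIPhiAlpha))
}

#' Run an ensemble of environments to steady state
#'
#' One proteome is sampled once and held fixed across all environments;
#' each environment is drawn (randomly, or targeted at scheduled index
#' values) and solved with [steadyState()].  Modes: \code{"full"} keeps the
#' sampled heterogeneous speeds and degradation rates;
#' \code{"no_degradation"} forces all degradation rates to zero;
#' \code{"homogeneous_speed"} forces every translation speed to the
#' realized non-ribosomal mean.
#'
#' @param config an [EnsembleConfig-class].
#' @param mode simulation mode (see above).
#' @param targets optional data.frame of per-environment index targets with
#'   columns \code{IChiK} and/or \code{IPhiAlpha} (1 row recycled, or one
#'   row per environment), e.g. from [sampleIndexSchedule()].
#' @param tol targeting tolerance passed to [sampleEnvironmentTargeted()].
#' @return an [EnsembleResult-class]; identical config and seed give
#'   bitwise-identical records.
#' @examples
#' cfg <- ensembleConfig(nGenes = 100, nEnvironments = 5, seed = 7)
#' res <- runEnsemble(cfg, mode = "no_degradation")
#' head(ensembleRecords(res))
#' @export
runEnsemble <- function(config, mode = c("full", "no_degradation",
                                         "homogeneous_speed"),
                        targets = NULL, tol = 1e-3) {
  mode <- match.arg(mode)
  params <- sampleProteome(config)
  if (mode == "no_degradation") {
    params <- ProteomeParams(k = translationSpeeds(params),
                             alpha = rep(0, nGenes(params)),
                             mR = ribosomeMass(params),
                             phi0 = inactiveFraction(params))
  } else if (mode == "homogeneous_speed") {
    params <- ProteomeParams(k = rep(meanSpeed(params), nGenes(params)),
                             alpha = degradationRates(params),
                             mR = ribosomeMass(params),
                             phi0 = inactiveFraction(params))
  }
  nE <- config@nEnvironments
  if (!is.null(targets)) {
    targets <- as.data.frame(targets)
    if (nrow(targets) == 1L) targets <- targets[rep(1L, nE), , drop = FALSE]
    if (nrow(targets) != nE)
      stop("targets must have 1 row or one row per environment")
  }
  rec <- vector("list", nE)
  for (i in seq_len(nE)) {
    envSeed <- .subSeed(config@seed, 1000 + i)
    env <- tryCatch({
      if (is.null(targets)) {
        sampleEnvironment(config, params, seed = envSeed)
      } else {
        tK <- if ("IChiK" %in% names(targets) && mode != "homogeneous_speed")
          targets$IChiK[i] else NULL
        tA <- if ("IPhiAlpha" %in% names(targets) && mode != "no_degradation")
          targets$IPhiAlpha[i] else NULL
        sampleEnvironmentTargeted(config, params, targetIChiK = tK,
                                  targetIPhiAlpha = tA, tol = tol,
                                  seed = envSeed)
      }
    }, error = function(e)
      stop(sprintf("environment %d: %s", i, conditionMessage(e))))
    st <- tryCatch(steadyState(params, env), error = function(e)
      stop(sprintf("environment %d: %s", i, conditionMessage(e))))
    rec[[i]] <- data.frame(env_id = i, mu_per_min = growthRate(st),
                           phi_R = phiR(st),
                           I_chi_k = allocationSpeedIndex(st),
                           I_phi_alpha = massDegradationIndex(st),
                           k_chi = weightedSpeedValue(st),
                           alpha_phi = weightedDegradationValue(st),
                           seed = envSeed)
  }
  new("EnsembleResult", records = do.call(rbind, rec), proteome = params,
      mode = mode, seed = config@seed)
}

#' Run an ensemble with Gaussian-distributed index targets
#'
#' Emulates growing cells in many environments whose correlation indices
#' scatter around common means: each environment's
#' \eqn{(I_{\chi,k}, I_{\phi,\alpha})} pair is drawn from independent
#' Gaussians and the environment is built by [sampleEnvironmentTargeted()].
#' Not every index pair is reachable — the feasible set depends on the
#' sampled proteome and slants (strong allocation-speed coupling leaves
#' little room to raise \eqn{I_{\phi,\alpha}}) — so pairs that prove
#' infeasible are redrawn, i.e. the realized targets follow the Gaussians
#' truncated to the feasible set.  Wide standard deviations give a
#' non-universal pool (scattered around many curves); narrow ones give a
#' universal pool on a single curve.
#'
#' @param config an [EnsembleConfig-class].
#' @param mode simulation mode as in [runEnsemble()].
#' @param meanIChiK,sdIChiK Gaussian mean and sd of the allocation-speed
#'   index draw.
#' @param meanIPhiAlpha,sdIPhiAlpha Gaussian mean and sd of the
#'   mass-degradation index draw.
#' @param maxRedraw redraw budget per environment (default 40).
#' @param tol targeting tolerance.
#' @return an [EnsembleResult-class]; the total number of redraws is
#'   attached to the records as attribute \code{"nRedrawn"}.
#' @export
runGaussianEnsemble <- function(config, mode = c("full", "no_degradation",
                                                 "homogeneous_speed"),
                                meanIChiK = 0.5, sdIChiK = 0.5,
                                meanIPhiAlpha = 0, sdIPhiAlpha = 0.5,
                                maxRedraw = 40L, tol = 1e-3) {
  mode <- match.arg(mode)
  params <- sampleProteome(config)
  if (mode == "no_degradation") {
    params <- ProteomeParams(k = translationSpeeds(params),
                             alpha = rep(0, nGenes(params)),
                             mR = ribosomeMass(params),
                             phi0 = inactiveFraction(params))
  } else if (mode == "homogeneous_speed") {
    params <- ProteomeParams(k = rep(meanSpeed(params), nGenes(params)),
                             alpha = degradationRates(params),
                             mR = ribosomeMass(params),
                             phi0 = inactiveFraction(params))
  }
  ## loose plausibility box so absurd tail draws do not waste the
  ## targeting budget; the slanted joint frontier is handled empirically
  box1 <- c(-0.45, 0.85); box2 <- c(-0.55, 0.45)
  nE <- config@nEnvironments
  rec <- vector("list", nE)
  nRedrawn <- 0L
  for (i in seq_len(nE)) {
    envSeed <- .subSeed(config@seed, 1000 + i)
    set.seed(.subSeed(config@seed, 2000000 + i))
    env <- NULL
    for (try in seq_len(maxRedraw)) {
      t1 <- stats::rnorm(1, meanIChiK, sdIChiK)
      t2 <- stats::rnorm(1, meanIPhiAlpha, sdIPhiAlpha)
      if (t1 < box1[1] || t1 > box1[2] || t2 < box2[1] || t2 > box2[2]) {
        nRedrawn <- nRedrawn + 1L
        next
      }
      env <- tryCatch(sampleEnvironmentTargeted(
        config, params,
        targetIChiK = if (mode != "homogeneous_speed") t1 else NULL,
        targetIPhiAlpha = if (mode != "no_degradation") t2 else NULL,
        tol = tol, maxAttempts = 1500, seed = .subSeed(envSeed, try)),
        error = function(e) NULL)
      if (!is.null(env)) break
      nRedrawn <- nRedrawn + 1L
    }
    if (is.null(env))
      stop(sprintf("environment %d: no feasible index target in %d draws",
                   i, maxRedraw))
    st <- steadyState(params, env)
    rec[[i]] <- data.frame(env_id = i, mu_per_min = growthRate(st),
                           phi_R = phiR(st),
                           I_chi_k = allocationSpeedIndex(st),
                           I_phi_alpha = massDegradationIndex(st),
                           k_chi = weightedSpeedValue(st),
                           alpha_phi = weightedDegradationValue(st),
                           seed = envSeed)
  }
  records <- do.call(rbind, rec)
  attr(records, "nRedrawn") <- nRedrawn
  new("EnsembleResult", records = records, proteome = params, mode = mode,
      seed = config@seed)
}

#' Write ensemble records to a TSV file
#'
#' @param result an [EnsembleResult-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeEnsemble <- function(result, path) {
  stopifnot(is(result, "EnsembleResult"))
  df <- ensembleRecords(result)
  df[] <- lapply(df, function(x) if (is.numeric(x)) format(x, digits = 17)
                 else x)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
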