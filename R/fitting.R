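#' Fit the growth-law curve to (mu, phi_R) data
#'
#' Least-squares fit of \eqn{\phi_R = (\mu + c_1)/(c_2\mu + c_3)} by
#' Levenberg-Marquardt, initialized from the constant-speed null: the
#' ordinary least-squares line \eqn{\phi_R \approx \mu/c_3 + c_1/c_3} with
#' \eqn{c_2 = 0}.  95\% confidence intervals are Jacobian-linearized
#' Student-t intervals at \eqn{n - 3} degrees of freedom; the reported RMSE
#' is \eqn{\sqrt{SS_{res}/n}}.
#'
#' @param data data.frame with columns \code{mu} (1/min, >= 0) and
#'   \code{phi_R} (in (0,1)); at least 4 rows.
#' @param init optional named start values \code{c(c1=, c2=, c3=)}.
#' @return a [GrowthLawFit-class].
#' @examples
#' cf <- GrowthLawCoefficients(1.5e-3, -1.3, 3.6e-2)
#' d <- generateGrowthLawDataset(cf, seq(1e-4, 6e-3, length.out = 10),
#'                               noiseSD = 0, seed = 1)
#' fitGrowthLaw(d)
#' @export
fitGrowthLaw <- function(data, init = NULL) {
  data <- as.data.frame(data)
  if (!all(c("mu", "phi_R") %in% names(data)))
    stop("data must have columns mu and phi_R")
  n <- nrow(data)
  if (n < 4L) stop("need at least 4 points for a 3-parameter fit")
  if (any(data$mu < 0)) stop("growth rates must be nonnegative")
  if (any(data$phi_R <= 0 | data$phi_R >= 1))
    stop("phi_R values must lie strictly in (0, 1)")
  if (is.null(init)) {
    ols <- stats::lm(phi_R ~ mu, data = data)
    slope <- unname(stats::coef(ols)[2])
    if (!is.finite(slope) || slope <= 0) slope <- 1 / mean(data$mu) * 0.1
    init <- c(c1 = unname(stats::coef(ols)[1]) / slope, c2 = 0,
              c3 = 1 / slope)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(phi_R ~ (mu + c1) / (c2 * mu + c3), data = data,
                      start = as.list(init),
                      control = minpack.lm::nls.lm.control(maxiter = 500,
                                                           ftol = 1e-15,
                                                           ptol = 1e-15)),
    error = function(e) stop("fit failure: ", conditionMessage(e)))
  est <- stats::coef(fit)
  den <- est["c2"] * range(data$mu) + est["c3"]
  if (any(den <= 0))
    stop(sprintf(
      "pole error: fitted denominator crosses zero inside the data range (pole at mu* = %.6g)",
      -est["c3"] / est["c2"]))
  V <- tryCatch(stats::vcov(fit), error = function(e)
    stop("fit failure: singular Jacobian (", conditionMessage(e), ")"))
  if (any(!is.finite(V))) stop("fit failure: singular Jacobian")
  se <- sqrt(diag(V))
  tq <- stats::qt(0.975, df = n - 3L)
  ci <- cbind(lower = est - tq * se, upper = est + tq * se)
  rownames(ci) <- names(est)
  new("GrowthLawFit", coefficients = est, ci = ci, vcov = V,
      rmse = sqrt(sum(stats::resid(fit)^2) / n), nObs = as.integer(n),
      data = data[, c("mu", "phi_R")])
}

#' Invert growth-law coefficients to biological parameters
#'
#' Given the degradation inputs \eqn{\alpha_R}, \eqn{\langle\alpha\rangle_\phi}
#' and the ribosome mass \eqn{m_R}, the three curve coefficients determine
#' \deqn{\langle k\rangle_\chi = m_R\,(c_3 - \langle\alpha\rangle_\phi +
#'   \alpha_R(1 - c_2)),\quad
#'   k_R = \frac{\langle k\rangle_\chi}{1 - c_2},\quad
#'   \phi_0 = \frac{(c_1 - \langle\alpha\rangle_\phi)\,m_R}
#'   {\langle k\rangle_\chi}.}
#' This is the exact inverse of [fullCoefficients()].
#'
#' @param c1,c2,c3 curve coefficients (\code{c2 < 1}).
#' @param alphaR ribosomal degradation rate, 1/min.
#' @param alphaPhi mass-fraction-weighted degradation rate, 1/min.
#' @param mR ribosome mass, Da.
#' @return named vector \code{c(phi0 = , kR = , kChi = )}.
#' @export
invertCoefficients <- function(c1, c2, c3, alphaR, alphaPhi, mR) {
  c1 <- unname(c1); c2 <- unname(c2); c3 <- unname(c3)
  if (c2 >= 1) stop("k_R undefined: c2 must be < 1")
  kChi <- mR * (c3 - alphaPhi + alphaR * (1 - c2))
  if (kChi <= 0)
    stop("infeasible coefficients: implied <k>_chi is not positive")
  c(phi0 = (c1 - alphaPhi) * mR / kChi, kR = kChi / (1 - c2), kChi = kChi)
}

#' Propagate coefficient confidence intervals to biological parameters
#'
#' Minimizes and maximizes each of the inversion maps
#' \eqn{\phi_0(c_1,c_2,c_3)}, \eqn{k_R(c_1,c_2,c_3)} and
#' \eqn{\langle k\rangle_\chi(c_1,c_2,c_3)} over the 3-dimensional box of
#' 95\% confidence intervals, by dense grid search (default 21 points per
#' axis) plus local box-constrained refinement from the best grid cell.
#' Grid points where the inversion is infeasible (\eqn{c_2 \ge 1} or
#' implied \eqn{\langle k\rangle_\chi \le 0}) are dropped; if any are, a
#' partial-infeasibility warning is raised and the bounds refer to the
#' feasible sub-box.
#'
#' @param fit a [GrowthLawFit-class].
#' @param alphaR,alphaPhi,mR inversion inputs as in [invertCoefficients()].
#' @param gridN grid points per axis (default 21).
#' @return 3 x 2 matrix of \code{lower}/\code{upper} bounds with rows
#'   \code{phi0}, \code{kR}, \code{kChi}.
#' @export
boundDerivedParams <- function(fit, alphaR = 0, alphaPhi = 0, mR,
                               gridN = 21L) {
  stopifnot(is(fit, "GrowthLawFit"))
  ci <- confint95(fit)
  axes <- lapply(1:3, function(i) seq(ci[i, 1], ci[i, 2],
                                      length.out = gridN))
  grid <- as.matrix(expand.grid(axes[[1]], axes[[2]], axes[[3]]))
  kChi <- mR * (grid[, 3] - alphaPhi + alphaR * (1 - grid[, 2]))
  feasible <- grid[, 2] < 1 & kChi > 0
  if (!any(feasible))
    stop("infeasible coefficients: no feasible point in the confidence box")
  if (!all(feasible))
    warning("confidence box is partially infeasible; bounds computed on the feasible sub-box")
  grid <- grid[feasible, , drop = FALSE]
  kChi <- kChi[feasible]
  maps <- cbind(phi0 = (grid[, 1] - alphaPhi) * mR / kChi,
                kR = kChi / (1 - grid[, 2]), kChi = kChi)

  refine <- function(start, mapIdx, maximize) {
    objFun <- function(p) {
      kc <- mR * (p[3] - alphaPhi + alphaR * (1 - p[2]))
      if (p[2] >= 1 || kc <= 0) return(if (maximize) -Inf else Inf)
      v <- switch(mapIdx, (p[1] - alphaPhi) * mR / kc, kc / (1 - p[2]), kc)
      if (maximize) -v else v
    }
    opt <- try(stats::optim(start, objFun, method = "L-BFGS-B",
                            lower = ci[, 1], upper = ci[, 2]),
               silent = TRUE)
    if (inherits(opt, "try-error")) return(objFun(start) * if (maximize) -1 else 1)
    if (maximize) -opt$value else opt$value
  }
  out <- matrix(NA_real_, 3, 2,
                dimnames = list(c("phi0", "kR", "kChi"),
                                c("lower", "upper")))
  for (j in 1:3) {
    iMin <- which.min(maps[, j]); iMax <- which.max(maps[, j])
    out[j, 1] <- min(maps[iMin, j], refine(grid[iMin, ], j, FALSE))
    out[j, 2] <- max(maps[iMax, j], refine(grid[iMax, ], j, TRUE))
  }
  out
}

#' Subsampling RMSE test of growth-law universality
#'
#' Repeatedly draws \code{nPoints} environments (without replacement) from
#' an ensemble, fits the growth-law curve to each draw and records the
#' RMSE.  A pool of environments sharing one pair of correlation indices
#' lies on one exact curve and yields near-zero RMSE; a pool with broadly
#' scattered indices does not, so the median RMSE measures how universal
#' the pool's growth law is.  Replicates whose fit fails are excluded and
#' counted.
#'
#' @param pool an [EnsembleResult-class] or data.frame with columns
#'   \code{mu_per_min} and \code{phi_R}.
#' @param nPoints points per replicate (default 20).
#' @param nReps number of replicates (default 5000).
#' @param seed RNG seed for the draws.
#' @return list with \code{rmse} (vector over successful replicates),
#'   \code{median}, and \code{nFailed}.
#' @export
subsampleRmse <- function(pool, nPoints = 20L, nReps = 5000L, seed = 1L) {
  if (is(pool, "EnsembleResult")) pool <- ensembleRecords(pool)
  pool <- as.data.frame(pool)
  if (nrow(pool) < nPoints)
    stop("pool must contain at least nPoints environments")
  set.seed(seed)
  rmse <- rep(NA_real_, nReps)
  for (r in seq_len(nReps)) {
    idx <- sample.int(nrow(pool), nPoints)
    d <- data.frame(mu = pool$mu_per_min[idx], phi_R = pool$phi_R[idx])
    f <- try(suppressWarnings(fitGrowthLaw(d)), silent = TRUE)
    if (!inherits(f, "try-error")) rmse[r] <- fitRMSE(f)
  }
  ok <- !is.na(rmse)
  list(rmse = rmse[ok], median = stats::median(rmse[ok]),
       nFailed = sum(!ok))
}

#' Predict the ribosomal fraction for measured conditions
#'
#' Given a condition's growth rate and its two correlation indices, builds
#' the weighted averages
#' \eqn{\langle k\rangle_\chi = \langle k\rangle(1 + I_{\chi,k})} and
#' \eqn{\langle\alpha\rangle_\phi = \langle\alpha\rangle(1 + I_{\phi,\alpha})}
#' and evaluates the growth-law curve.  A common inactive fraction
#' \eqn{\phi_0} can be imposed across conditions via \code{phi0} (e.g. a
#' shared 0.048 for budding-yeast panels).
#'
#' @param params a [ProteomeParams-class] supplying \eqn{k_R},
#'   \eqn{\alpha_R}, \eqn{\langle k\rangle}, \eqn{\langle\alpha\rangle},
#'   \eqn{m_R} and the default \eqn{\phi_0}.
#' @param mu growth rate(s), 1/min.
#' @param IChiK,IPhiAlpha correlation indices per condition (> -1;
#'   recycled against \code{mu}).
#' @param phi0 optional shared inactive fraction overriding the proteome's.
#' @return predicted ribosomal fraction(s).
#' @export
predictPhiRForConditions <- function(params, mu, IChiK, IPhiAlpha,
                                     phi0 = NULL) {
  m <- max(length(mu), length(IChiK), length(IPhiAlpha))
  mu <- rep_len(mu, m); IChiK <- rep_len(IChiK, m)
  IPhiAlpha <- rep_len(IPhiAlpha, m)
  if (any(IChiK <= -1) || any(IPhiAlpha <= -1))
    stop("indices must be > -1")
  if (!is.null(phi0))
    params <- ProteomeParams(k = translationSpeeds(params),
                             alpha = degradationRates(params),
                             mR = ribosomeMass(params), phi0 = phi0)
  vapply(seq_len(m), function(i) {
    cf <- fullCoefficients(params, kChi = meanSpeed(params) * (1 + IChiK[i]),
                           alphaPhi = meanDegradation(params) *
                             (1 + IPhiAlpha[i]))
    phiRGrowthLaw(mu[i], cf)
  }, numeric(1))
}

#' Correlate predicted and measured proteome compositions
#'
#' Predicts per-protein mass fractions from the allocation vector at the
#' measured growth rate and returns the Pearson correlation with measured
#' non-ribosomal fractions, for the full prediction and two ablations:
#' no degradation (\eqn{\alpha_i = 0}) and homogeneous speed
#' (\eqn{k_i = \langle k\rangle}).
#'
#' @param params a [ProteomeParams-class].
#' @param env a [CellEnvironment-class].
#' @param mu measured growth rate, 1/min.
#' @param measuredPhi measured full mass-fraction vector (element 1
#'   ribosomal), aligned with the proteome.
#' @return named vector \code{c(full = , alpha_zero = , k_homogeneous = )}
#'   of Pearson correlations over non-ribosomal proteins.
#' @export
evaluatePhiPrediction <- function(params, env, mu, measuredPhi) {
  if (length(measuredPhi) != nGenes(params))
    stop("measuredPhi and proteome sizes differ")
  if (nGenes(params) - 1L < 3L)
    stop("undefined correlation: need at least 3 common non-ribosomal genes")
  n <- nGenes(params)
  ablAlpha <- ProteomeParams(k = translationSpeeds(params),
                             alpha = rep(0, n), mR = ribosomeMass(params),
                             phi0 = inactiveFraction(params))
  ablK <- ProteomeParams(k = rep(meanSpeed(params), n),
                         alpha = degradationRates(params),
                         mR = ribosomeMass(params),
                         phi0 = inactiveFraction(params))
  rho <- function(p) stats::cor(predictPhi(p, env, mu)[-1], measuredPhi[-1])
  c(full = rho(params), alpha_zero = rho(ablAlpha), k_homogeneous = rho(ablK))
}
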