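#' Relative-covariance correlation index
#'
#' The dimensionless index used to characterize an environment:
#' \deqn{I = \frac{\langle w_i x_i\rangle - \langle w\rangle\langle x\rangle}
#'   {\langle w\rangle\langle x\rangle}}
#' where the brackets are arithmetic means over non-ribosomal proteins.
#' Because the weights are normalized, this equals the ratio of weighted to
#' arithmetic mean of \code{values}, minus 1.  With allocation weights and
#' translation speeds it gives \eqn{I_{\chi,k}}; with mass-fraction weights
#' and degradation rates it gives \eqn{I_{\phi,\alpha}}.  For nonnegative
#' inputs the index is bounded below by -1.
#'
#' @param weights nonnegative vector summing to 1 (renormalized non-ribosomal
#'   allocations or mass fractions).
#' @param values positive-mean vector of the same length (speeds or rates).
#' @return the dimensionless index.
#' @examples
#' correlationIndex(c(0.5, 0.3, 0.2), c(2, 4, 6))  # -0.15
#' @export
correlationIndex <- function(weights, values) {
  if (length(weights) != length(values))
    stop("dimension error: weights and values must have the same length")
  if (length(weights) < 2L)
    stop("need at least 2 entries")
  if (any(weights < 0))
    stop("weights must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-6)
    stop("weights must sum to 1")
  mx <- mean(values)
  if (mx <= 0)
    stop("undefined index: values must have a positive mean")
  mw <- mean(weights)
  (mean(weights * values) - mw * mx) / (mw * mx)
}

#' Allocation-weighted mean translation speed
#'
#' \eqn{\langle k\rangle_\chi = \sum_{i \ge 2} k_i \tilde\chi_i} over
#' non-ribosomal proteins, where \eqn{\tilde\chi_i = \chi_i/(1-\chi_R)}.
#' Satisfies the identity
#' \eqn{\langle k\rangle_\chi = \langle k\rangle(1 + I_{\chi,k})} exactly.
#'
#' @param params a [ProteomeParams-class].
#' @param env a [CellEnvironment-class] with \eqn{\chi_R < 1}.
#' @return the weighted speed in Da/min.
#' @export
weightedSpeed <- function(params, env) {
  ct <- chiTilde(env)
  k <- translationSpeeds(params)
  if (length(ct) != length(k) - 1L)
    stop("environment and proteome sizes differ")
  sum(k[-1] * ct)
}

#' Mass-fraction-weighted mean degradation rate
#'
#' \eqn{\langle\alpha\rangle_\phi = \sum_{i\ge 2}\alpha_i\tilde\phi_i} over
#' non-ribosomal proteins, with \eqn{\tilde\phi_i = \phi_i/(1-\phi_R)}.
#' Satisfies
#' \eqn{\langle\alpha\rangle_\phi = \langle\alpha\rangle(1+I_{\phi,\alpha})}
#' exactly.
#'
#' @param params a [ProteomeParams-class].
#' @param phi a full mass-fraction vector (element 1 ribosomal) or a
#'   [SteadyState-class].
#' @return the weighted degradation rate in 1/min.
#' @export
weightedDegradation <- function(params, phi) {
  if (is(phi, "SteadyState")) phi <- massFractions(phi)
  if (length(phi) != nGenes(params))
    stop("phi and proteome sizes differ")
  if (phi[1] >= 1)
    stop("degenerate state: phi_R = 1 leaves no non-ribosomal mass")
  pt <- phi[-1] / (1 - phi[1])
  sum(degradationRates(params)[-1] * pt)
}

#' Hill-form growth-law coefficients (degradation-free model)
#'
#' In the degradation-free model the growth law is exactly a Hill function,
#' \eqn{\phi_R = \mu/(a\mu + b) + \phi_0}, with
#' \deqn{a = \frac{k_R - \langle k\rangle_\chi}
#'  {k_R(1-\phi_0) + \langle k\rangle_\chi\phi_0}, \qquad
#'  b = \frac{k_R\langle k\rangle_\chi}
#'  {m_R\,[k_R(1-\phi_0) + \langle k\rangle_\chi\phi_0]}.}
#' The sign of \eqn{a} follows \eqn{k_R - \langle k\rangle_\chi}: slower
#' ribosomal-protein translation (\eqn{a < 0}) bends the curve upward at
#' slow growth.
#'
#' @param params a [ProteomeParams-class]; its degradation rates are ignored.
#' @param kChi allocation-weighted non-ribosomal translation speed, Da/min.
#' @return named vector \code{c(a = , b = )}, \code{b} in 1/min.
#' @export
hillCoefficients <- function(params, kChi) {
  kR <- translationSpeeds(params)[1]
  phi0 <- inactiveFraction(params)
  den <- kR * (1 - phi0) + kChi * phi0
  c(a = (kR - kChi) / den, b = kR * kChi / (ribosomeMass(params) * den))
}

#' Linear growth-law coefficients (homogeneous-speed model)
#'
#' With one common translation speed \eqn{k} and finite heterogeneous
#' degradation rates the growth law is the straight line
#' \eqn{\phi_R = (\mu + c)/(k/m_R + d) + \phi_0}, with
#' \eqn{c = \langle\alpha\rangle_\phi(1-\phi_0) + \alpha_R\phi_0} and
#' \eqn{d = \langle\alpha\rangle_\phi - \alpha_R}.  Degradation lowers the
#' slope and raises the intercept relative to the constant-speed baseline:
#' a finite fraction of ribosomes keeps translating at zero growth.
#'
#' @param params a [ProteomeParams-class] (supplies \eqn{\alpha_R},
#'   \eqn{\phi_0}).
#' @param alphaPhi mass-fraction-weighted degradation rate, 1/min.
#' @return named vector \code{c(c = , d = )}, both 1/min.
#' @export
linearCoefficients <- function(params, alphaPhi) {
  alphaR <- degradationRates(params)[1]
  phi0 <- inactiveFraction(params)
  c(c = alphaPhi * (1 - phi0) + alphaR * phi0, d = alphaPhi - alphaR)
}

#' Growth-law coefficients of the full model
#'
#' With both heterogeneous speeds and finite degradation the growth law is
#' \eqn{\phi_R = (\mu + c_1)/(c_2\mu + c_3)} with
#' \deqn{c_1 = \frac{\langle k\rangle_\chi\phi_0}{m_R} +
#'   \langle\alpha\rangle_\phi,\quad
#'   c_2 = 1 - \frac{\langle k\rangle_\chi}{k_R},\quad
#'   c_3 = \langle\alpha\rangle_\phi -
#'   \frac{\alpha_R\langle k\rangle_\chi}{k_R} +
#'   \frac{\langle k\rangle_\chi}{m_R}.}
#' With all degradation rates zero the curve is algebraically identical to
#' the Hill form from [hillCoefficients()].
#'
#' @param params a [ProteomeParams-class].
#' @param kChi allocation-weighted translation speed, Da/min (> 0).
#' @param alphaPhi mass-fraction-weighted degradation rate, 1/min.
#' @return a [GrowthLawCoefficients-class].
#' @examples
#' pp <- ProteomeParams(k = c(2.07e4, 4.8e4), alpha = c(4.83e-4, 1.1e-3))
#' fullCoefficients(pp, kChi = 4.8e4, alphaPhi = 1.1e-3)
#' @export
fullCoefficients <- function(params, kChi, alphaPhi) {
  if (kChi <= 0) stop("kChi must be positive")
  kR <- translationSpeeds(params)[1]
  alphaR <- degradationRates(params)[1]
  mR <- ribosomeMass(params)
  phi0 <- inactiveFraction(params)
  GrowthLawCoefficients(c1 = kChi * phi0 / mR + alphaPhi,
                        c2 = 1 - kChi / kR,
                        c3 = alphaPhi - alphaR * kChi / kR + kChi / mR)
}

#' Evaluate the growth-law curve
#'
#' \eqn{\phi_R(\mu) = (\mu + c_1)/(c_2\mu + c_3)}.  The curve has a pole at
#' \eqn{\mu^* = -c_3/c_2}; evaluation on the wrong side of the pole is a
#' domain error.
#'
#' @param mu growth rate(s), 1/min.
#' @param coeffs a [GrowthLawCoefficients-class].
#' @return ribosomal proteome fraction(s), same length as \code{mu}.
#' @export
phiRGrowthLaw <- function(mu, coeffs) {
  stopifnot(is(coeffs, "GrowthLawCoefficients"))
  den <- coeffs@c2 * mu + coeffs@c3
  if (any(den <= 0)) {
    pole <- if (coeffs@c2 != 0) -coeffs@c3 / coeffs@c2 else NA_real_
    stop(sprintf(
      "domain error: denominator c2*mu + c3 <= 0 (pole at mu* = %.6g /min)",
      pole))
  }
  (mu + coeffs@c1) / den
}

#' Shape diagnostics of a growth-law curve
#'
#' The curve is monotonically increasing iff the discriminant
#' \eqn{c_3 - c_1 c_2 > 0} and convex iff additionally \eqn{c_2 < 0}
#' (second derivative proportional to \eqn{(c_1c_2 - c_3)c_2}).  In terms of
#' the biological parameters the discriminant is
#' \deqn{c_3 - c_1c_2 = \frac{\langle k\rangle_\chi(1-\phi_0)}{m_R} +
#'  \frac{\langle k\rangle_\chi^2\phi_0}{k_R m_R} +
#'  \frac{\langle k\rangle_\chi(\langle\alpha\rangle_\phi-\alpha_R)}{k_R},}
#' positive whenever \eqn{\alpha_R \le \langle\alpha\rangle_\phi}; convexity
#' additionally requires \eqn{k_R < \langle k\rangle_\chi}.
#'
#' @param coeffs a [GrowthLawCoefficients-class].
#' @return list with logical \code{increasing}, \code{convex} and the
#'   numeric \code{discriminant} \eqn{c_3 - c_1c_2}.
#' @export
curveShape <- function(coeffs) {
  stopifnot(is(coeffs, "GrowthLawCoefficients"))
  disc <- coeffs@c3 - coeffs@c1 * coeffs@c2
  list(increasing = disc > 0,
       convex = (coeffs@c1 * coeffs@c2 - coeffs@c3) * coeffs@c2 > 0,
       discriminant = disc)
}

#' Steady-state proteome composition at a given growth rate
#'
#' Mass-action balance of synthesis, dilution and degradation gives
#' \deqn{\phi_i = \frac{k_i\chi_i/(\mu+\alpha_i)}
#'  {\sum_j k_j\chi_j/(\mu+\alpha_j)},}
#' normalized to sum to 1 by construction.  At fixed allocation, a faster
#' translation speed raises a protein's mass fraction and a faster
#' degradation rate lowers it.
#'
#' @param params a [ProteomeParams-class].
#' @param env a [CellEnvironment-class].
#' @param mu growth rate, 1/min; must satisfy \code{mu + alpha_i > 0} for
#'   all proteins.
#' @return numeric vector of mass fractions (element 1 ribosomal).
#' @export
predictPhi <- function(params, env, mu) {
  k <- translationSpeeds(params)
  alpha <- degradationRates(params)
  chi <- allocations(env)
  if (length(chi) != length(k))
    stop("environment and proteome sizes differ")
  if (any(mu + alpha <= 0))
    stop("domain error: mu + alpha_i must be positive for every protein")
  w <- k * chi / (mu + alpha)
  w / sum(w)
}

## self-consistency function whose root is the steady-state growth rate:
## g(mu) = k_R chi_R (1 - phi0/phi_R(mu)) / m_R - alpha_R - mu,
## with phi_R(mu) from the normalized composition map above.
.growthResidual <- function(mu, k, alpha, chi, mR, phi0) {
  kc <- k * chi
  W <- kc / outer(alpha, mu, "+")          # proteins x trial rates
  pR <- W[1, ] / colSums(W)
  kc[1] * (1 - phi0 / pR) / mR - alpha[1] - mu
}

#' Solve the protein-synthesis model for its steady state
#'
#' Reduces the coupled (growth rate, composition) fixed point to a
#' one-dimensional root problem: the composition at any trial growth rate
#' follows from [predictPhi()], and the trial rate must equal the ribosome
#' self-replication rate
#' \eqn{\mu = k_R\chi_R(1-\phi_0/\phi_R)/m_R - \alpha_R}.  The residual is
#' scanned on a 512-point grid over
#' \eqn{(-\min_i\alpha_i + 10^{-12},\; k_R\chi_R/m_R)} (the upper end is a
#' rigorous bound on the growth rate) and each sign change is polished by
#' Brent's method to near machine precision.  A negative solved growth
#' rate (degradation-dominated regime) is returned with a warning.
#'
#' With heterogeneous degradation the residual generically has a second,
#' subdominant root just above \eqn{-\min_i\alpha_i}, where the
#' composition is taken over by the slowest-degrading gene.  The mass
#' dynamics are linear, so steady compositions are eigenvectors and the
#' dynamics converge to the eigenvector of the largest eigenvalue: only
#' the largest root is dynamically stable (verified against
#' [integrateDynamics()] in the test suite).  \code{multiRoot = "largest"}
#' (default) therefore selects it; \code{multiRoot = "error"} fails
#' loudly, reporting all roots.
#'
#' At the solution the normalization residual
#' \eqn{|1 - (\phi_R-\phi_0)/m_R\sum_i k_i\chi_i/(\mu+\alpha_i)|}
#' vanishes identically, and the solved \eqn{\phi_R} equals the closed-form
#' curve [phiRGrowthLaw()] evaluated with the realized
#' \eqn{\langle k\rangle_\chi} and \eqn{\langle\alpha\rangle_\phi}.
#'
#' @param params a [ProteomeParams-class].
#' @param env a [CellEnvironment-class] with \eqn{0 < \chi_R < 1}.
#' @param nGrid number of scan-grid points (default 512).
#' @param multiRoot policy when several roots are detected:
#'   \code{"largest"} (the dynamically stable branch) or \code{"error"}.
#' @return a [SteadyState-class].
#' @examples
#' pp <- ProteomeParams(k = rep(4.8e4, 3), alpha = rep(0, 3), mR = 1.4e6)
#' st <- steadyState(pp, CellEnvironment(c(0.3, 0.35, 0.35)))
#' growthRate(st)   # 7.5429e-3 /min
#' @export
steadyState <- function(params, env, nGrid = 512L,
                        multiRoot = c("largest", "error")) {
  multiRoot <- match.arg(multiRoot)
  k <- translationSpeeds(params)
  alpha <- degradationRates(params)
  mR <- ribosomeMass(params)
  phi0 <- inactiveFraction(params)
  chi <- allocations(env)
  if (length(chi) != length(k))
    stop("environment and proteome sizes differ")
  cR <- chi[1]
  if (cR <= 0)
    stop("degenerate environment: chi_R = 0 (no ribosome self-production)")
  if (cR >= 1)
    stop("degenerate environment: chi_R = 1 (no non-ribosomal allocation)")

  muMin <- -min(alpha) + 1e-12
  muMax <- k[1] * cR / mR
  if (muMax <= muMin)
    stop("no steady state: search interval is empty")
  ## log-spaced offsets above muMin concentrate points near the singular end
  span <- muMax - muMin
  grid <- muMin + exp(seq(log(span * 1e-9), log(span), length.out = nGrid))
  grid[nGrid] <- muMax
  gv <- .growthResidual(grid, k, alpha, chi, mR, phi0)
  ok <- is.finite(gv)
  grid <- grid[ok]; gv <- gv[ok]
  sgn <- sign(gv)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  exact <- which(gv == 0)
  if (length(flips) + length(exact) == 0L)
    stop("no steady state: growth-rate residual has no sign change on the search interval")
  roots <- grid[exact]
  for (i in flips) {
    r <- stats::uniroot(.growthResidual, c(grid[i], grid[i + 1]),
                        k = k, alpha = alpha, chi = chi, mR = mR,
                        phi0 = phi0, tol = .Machine$double.eps)
    roots <- c(roots, r$root)
  }
  if (length(roots) > 1L && multiRoot == "error")
    stop(sprintf("ambiguous steady state: multiple roots detected (mu = %s)",
                 paste(signif(roots, 8), collapse = ", ")))
  mu <- max(roots)

  phi <- predictPhi(params, env, mu)
  ct <- chi[-1] / (1 - cR)
  pt <- phi[-1] / (1 - phi[1])
  kChi <- sum(k[-1] * ct)
  alphaPhi <- sum(alpha[-1] * pt)
  muI <- k * chi * (phi[1] - phi0) / (mR * phi) - alpha
  if (mu < 0)
    warning("negative steady-state growth rate (degradation-dominated regime)")
  new("SteadyState", mu = mu, phi = phi, kChi = kChi, alphaPhi = alphaPhi,
      IChiK = correlationIndex(ct, k[-1]),
      IPhiAlpha = if (mean(alpha[-1]) > 0)
        correlationIndex(pt, alpha[-1]) else 0,
      muPerProtein = muI, negativeGrowth = mu < 0)
}

#' Integrate the protein-mass dynamics
#'
#' The primitive mass-balance dynamics behind the steady-state model:
#' \deqn{\frac{dM_i}{dt} = k_i\chi_i(R - R_0) - \alpha_i M_i,}
#' with ribosome count \eqn{R = M_1/m_R} and inactive count
#' \eqn{R_0 = \phi_0 M/m_R}.  The system is linear, its dominant eigenvalue
#' is the steady-state growth rate, and the mass-fraction vector converges
#' to the [steadyState()] composition; it serves as an independent dynamical
#' cross-check of the solver.
#'
#' @param params a [ProteomeParams-class].
#' @param env a [CellEnvironment-class].
#' @param M0 positive initial per-protein masses, Da.
#' @param times increasing vector of output times, min.
#' @param rtol,atol integrator tolerances passed to [deSolve::ode()].
#' @return matrix with a \code{time} column and one column per protein mass.
#'   A transient with fewer active ribosomes than inactive ones at the start
#'   (\eqn{R < R_0}) is permitted but flagged with a warning.
#' @export
integrateDynamics <- function(params, env, M0, times, rtol = 1e-10,
                              atol = 1e-12) {
  k <- translationSpeeds(params)
  alpha <- degradationRates(params)
  mR <- ribosomeMass(params)
  phi0 <- inactiveFraction(params)
  chi <- allocations(env)
  if (length(M0) != length(k))
    stop("M0 and proteome sizes differ")
  if (any(M0 <= 0)) stop("all initial masses must be positive")
  if (M0[1] / mR - phi0 * sum(M0) / mR < 0)
    warning("initial state has R < R0 (transient ribosome deficit)")
  deriv <- function(t, M, parms) {
    active <- M[1] / mR - phi0 * sum(M) / mR
    list(k * chi * active - alpha * M)
  }
  out <- deSolve::ode(y = M0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol,
                      atol = atol * max(M0))
  if (attr(out, "istate")[1] < 0) stop("ODE integrator failed")
  unname(as.matrix(out))
}
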