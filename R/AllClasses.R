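#' @import methods
NULL

#' Per-protein biochemical parameters of a proteome
#'
#' Fixed (environment-independent) biochemistry of a coarse-grained cell with
#' \code{N} proteins.  Index 1 is reserved for the coarse-grained ribosomal
#' protein, whose translation speed and degradation rate are the effective
#' values averaged over all ribosomal proteins.
#'
#' @slot k numeric vector of per-protein translation speeds, Da of amino acids
#'   polymerized per ribosome per minute; \code{k[1]} is the ribosomal value
#'   \eqn{k_R}.
#' @slot alpha numeric vector of per-protein first-order degradation rates,
#'   1/min; \code{alpha[1]} is \eqn{\alpha_R}.
#' @slot mR amino-acid mass of one ribosome's protein complement, Da.
#' @slot phi0 mass fraction of inactive (non-translating) ribosomes,
#'   dimensionless, assumed environment-independent.
#'
#' @seealso [ProteomeParams()] for the constructor, [steadyState()].
#' @exportClass ProteomeParams
setClass("ProteomeParams",
  representation(k = "numeric", alpha = "numeric", mR = "numeric",
                 phi0 = "numeric"))

setValidity("ProteomeParams", function(object) {
  msg <- character(0)
  n <- length(object@k)
  if (n < 2L)
    msg <- c(msg, "need at least 2 proteins (ribosomal + 1 non-ribosomal)")
  if (length(object@alpha) != n)
    msg <- c(msg, "k and alpha must have the same length")
  if (any(!is.finite(object@k)) || any(object@k <= 0))
    msg <- c(msg, "all translation speeds k must be finite and > 0")
  if (any(!is.finite(object@alpha)) || any(object@alpha < 0))
    msg <- c(msg, "all degradation rates alpha must be finite and >= 0")
  if (length(object@mR) != 1L || !is.finite(object@mR) || object@mR <= 0)
    msg <- c(msg, "mR must be a single positive number")
  if (length(object@phi0) != 1L || !is.finite(object@phi0) ||
      object@phi0 < 0 || object@phi0 >= 1)
    msg <- c(msg, "phi0 must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct a ProteomeParams object
#'
#' @param k numeric vector of translation speeds (Da/min); element 1 is the
#'   coarse-grained ribosomal protein \eqn{k_R}.
#' @param alpha numeric vector of degradation rates (1/min); element 1 is
#'   \eqn{\alpha_R}.  Defaults to no degradation.
#' @param mR ribosome amino-acid mass in Da (default the full ribosomal
#'   protein mass of budding yeast, 1.40e6 Da).
#' @param phi0 inactive-ribosome mass fraction (default 0.08).
#' @return a [ProteomeParams-class] object.
#' @examples
#' pp <- ProteomeParams(k = c(2.07e4, 4.8e4, 5.2e4), alpha = c(0, 0, 0))
#' meanSpeed(pp)
#' @export
ProteomeParams <- function(k, alpha = rep(0, length(k)), mR = 1.40e6,
                           phi0 = 0.08) {
  new("ProteomeParams", k = as.numeric(k), alpha = as.numeric(alpha),
      mR = as.numeric(mR), phi0 = as.numeric(phi0))
}

#' A growth environment: the ribosome allocation vector
#'
#' One environment is one allocation vector \eqn{\chi} over proteins:
#' \code{chi[i]} is the fraction of active ribosomes translating mRNAs of
#' protein \code{i}; \code{chi[1]} is the ribosomal allocation \eqn{\chi_R}.
#'
#' @slot chi numeric vector of allocation fractions summing to 1.
#' @seealso [CellEnvironment()], [chiTilde()], [steadyState()].
#' @exportClass CellEnvironment
setClass("CellEnvironment", representation(chi = "numeric"))

setValidity("CellEnvironment", function(object) {
  msg <- character(0)
  if (length(object@chi) < 2L)
    msg <- c(msg, "need at least 2 allocation entries")
  if (any(!is.finite(object@chi)) || any(object@chi < 0))
    msg <- c(msg, "all allocations chi must be finite and >= 0")
  if (abs(sum(object@chi) - 1) > 1e-12)
    msg <- c(msg, "allocations chi must sum to 1 (tolerance 1e-12)")
  if (length(msg)) msg else TRUE
})

#' Construct a CellEnvironment
#'
#' @param chi numeric vector of ribosome allocation fractions (element 1 is
#'   the ribosomal allocation \eqn{\chi_R}).  Must sum to 1 to within 1e-12
#'   unless \code{normalize = TRUE}.
#' @param normalize if TRUE, rescale \code{chi} to sum exactly to 1.
#' @return a [CellEnvironment-class] object.
#' @examples
#' env <- CellEnvironment(c(0.3, 0.4, 0.3))
#' chiR(env)
#' @export
CellEnvironment <- function(chi, normalize = FALSE) {
  chi <- as.numeric(chi)
  if (normalize) {
    s <- sum(chi)
    if (!is.finite(s) || s <= 0) stop("cannot normalize: sum(chi) <= 0")
    chi <- chi / s
  }
  new("CellEnvironment", chi = chi)
}

#' Steady state of the protein-synthesis model
#'
#' The solved balanced-growth state for one proteome in one environment:
#' growth rate, proteome composition, realized environment-weighted averages
#' and correlation indices.
#'
#' @slot mu steady-state growth rate, 1/min.
#' @slot phi per-protein mass fractions (element 1 is \eqn{\phi_R}).
#' @slot kChi allocation-weighted mean translation speed over non-ribosomal
#'   proteins \eqn{\langle k\rangle_\chi}, Da/min.
#' @slot alphaPhi mass-fraction-weighted mean degradation rate
#'   \eqn{\langle\alpha\rangle_\phi}, 1/min.
#' @slot IChiK correlation index between allocations and speeds.
#' @slot IPhiAlpha correlation index between mass fractions and degradation
#'   rates.
#' @slot muPerProtein per-protein growth-rate diagnostics; all equal
#'   \code{mu} at a valid steady state.
#' @slot negativeGrowth TRUE when the solved growth rate is negative
#'   (degradation-dominated regime).
#' @exportClass SteadyState
setClass("SteadyState",
  representation(mu = "numeric", phi = "numeric", kChi = "numeric",
                 alphaPhi = "numeric", IChiK = "numeric",
                 IPhiAlpha = "numeric", muPerProtein = "numeric",
                 negativeGrowth = "logical"))

setValidity("SteadyState", function(object) {
  msg <- character(0)
  if (abs(sum(object@phi) - 1) > 1e-10)
    msg <- c(msg, "mass fractions phi must sum to 1 (tolerance 1e-10)")
  if (any(object@phi < 0))
    msg <- c(msg, "mass fractions must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Coefficients of the general growth-law curve
#'
#' The rational growth-law curve \eqn{\phi_R = (\mu + c_1)/(c_2\mu + c_3)}
#' relating the ribosomal proteome fraction to the growth rate.  \eqn{c_2}
#' sets the nonlinearity and is proportional to
#' \eqn{k_R - \langle k\rangle_\chi}: slower ribosomal-protein translation
#' bends the curve upward at slow growth.
#'
#' @slot c1 1/min. @slot c2 dimensionless. @slot c3 1/min.
#' @seealso [fullCoefficients()], [phiRGrowthLaw()], [curveShape()].
#' @exportClass GrowthLawCoefficients
setClass("GrowthLawCoefficients",
  representation(c1 = "numeric", c2 = "numeric", c3 = "numeric"))

setValidity("GrowthLawCoefficients", function(object) {
  ok <- vapply(list(object@c1, object@c2, object@c3),
               function(x) length(x) == 1L && is.finite(x), logical(1))
  if (all(ok)) TRUE else "c1, c2, c3 must each be a single finite number"
})

#' Construct GrowthLawCoefficients directly
#'
#' Usually built from biological parameters via [fullCoefficients()]; this
#' constructor takes the three curve coefficients as-is (e.g. from a fit).
#'
#' @param c1,c2,c3 curve coefficients (\code{c1}, \code{c3} in 1/min,
#'   \code{c2} dimensionless).
#' @return a [GrowthLawCoefficients-class] object.
#' @export
GrowthLawCoefficients <- function(c1, c2, c3) {
  new("GrowthLawCoefficients", c1 = as.numeric(c1), c2 = as.numeric(c2),
      c3 = as.numeric(c3))
}

#' Result of fitting the growth-law curve to data
#'
#' @slot coefficients named numeric vector (c1, c2, c3) of point estimates.
#' @slot ci 3 x 2 matrix of 95\% confidence limits (rows c1, c2, c3).
#' @slot vcov 3 x 3 linearized covariance matrix of the estimates.
#' @slot rmse root mean squared residual of the ribosomal fraction.
#' @slot nObs number of observations used.
#' @slot data the fitted (mu, phi_R) data.
#' @exportClass GrowthLawFit
setClass("GrowthLawFit",
  representation(coefficients = "numeric", ci = "matrix", vcov = "matrix",
                 rmse = "numeric", nObs = "integer", data = "data.frame"))

#' Configuration of a proteome/environment ensemble
#'
#' Defaults are the study conditions used throughout: 4000 genes, lognormal
#' speeds and degradation rates with the budding-yeast means
#' (\eqn{k_R} = 2.07e4, \eqn{\langle k\rangle} = 4.80e4 Da/min,
#' \eqn{\alpha_R} = 4.83e-4, \eqn{\langle\alpha\rangle} = 1.10e-3 /min),
#' unit coefficients of variation, \eqn{\phi_0} = 0.08, ribosome mass
#' 1.40e6 Da and ribosomal allocations drawn uniformly on (0.05, 0.45).
#'
#' @slot nGenes number of proteins (including the coarse-grained ribosomal
#'   protein).
#' @slot meanK,kR mean non-ribosomal and ribosomal translation speed, Da/min.
#' @slot meanAlpha,alphaR mean non-ribosomal and ribosomal degradation rate,
#'   1/min.
#' @slot cvK,cvAlpha,cvChi coefficients of variation of the lognormal draws.
#' @slot phi0 inactive-ribosome fraction.
#' @slot mR ribosome mass, Da.
#' @slot chiRRange interval from which ribosomal allocations are drawn.
#' @slot nEnvironments number of environments per ensemble.
#' @slot seed master seed; proteome, environments and noise consume
#'   documented substreams derived from it.
#' @exportClass EnsembleConfig
setClass("EnsembleConfig",
  representation(nGenes = "integer", meanK = "numeric", kR = "numeric",
                 meanAlpha = "numeric", alphaR = "numeric", cvK = "numeric",
                 cvAlpha = "numeric", cvChi = "numeric", phi0 = "numeric",
                 mR = "numeric", chiRRange = "numeric",
                 nEnvironments = "integer", seed = "integer"))

setValidity("EnsembleConfig", function(object) {
  msg <- character(0)
  if (object@nGenes < 2L) msg <- c(msg, "nGenes must be >= 2")
  if (any(c(object@meanK, object@kR, object@mR) <= 0))
    msg <- c(msg, "speeds and mR must be positive")
  if (any(c(object@meanAlpha, object@alphaR) < 0))
    msg <- c(msg, "degradation rates must be nonnegative")
  if (any(c(object@cvK, object@cvAlpha, object@cvChi) <= 0))
    msg <- c(msg, "all coefficients of variation must be > 0")
  if (object@phi0 < 0 || object@phi0 >= 1)
    msg <- c(msg, "phi0 must lie in [0, 1)")
  r <- object@chiRRange
  if (length(r) != 2L || r[1] <= 0 || r[2] >= 1 || r[1] > r[2])
    msg <- c(msg, "chiRRange must be an interval inside (0, 1)")
  if (object@nEnvironments < 1L) msg <- c(msg, "nEnvironments must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct an EnsembleConfig
#'
#' @param nGenes number of proteins, default 4000.
#' @param meanK arithmetic mean non-ribosomal translation speed, Da/min.
#' @param kR ribosomal translation speed, Da/min.
#' @param meanAlpha arithmetic mean non-ribosomal degradation rate, 1/min.
#' @param alphaR ribosomal degradation rate, 1/min.
#' @param cvK,cvAlpha,cvChi coefficients of variation of the lognormal draws
#'   (defaults 1).
#' @param phi0 inactive-ribosome fraction, default 0.08.
#' @param mR ribosome mass, Da, default 1.40e6.
#' @param chiRRange interval for the uniform ribosomal-allocation draw.
#' @param nEnvironments number of environments, default 100.
#' @param seed master seed, default 1.
#' @return an [EnsembleConfig-class] object.
#' @examples
#' cfg <- ensembleConfig(nGenes = 200, nEnvironments = 10)
#' @export
ensembleConfig <- function(nGenes = 4000L, meanK = 4.80e4, kR = 2.07e4,
                           meanAlpha = 1.10e-3, alphaR = 4.83e-4,
                           cvK = 1.0, cvAlpha = 1.0, cvChi = 1.0,
                           phi0 = 0.08, mR = 1.40e6,
                           chiRRange = c(0.05, 0.45),
                           nEnvironments = 100L, seed = 1L) {
  new("EnsembleConfig", nGenes = as.integer(nGenes), meanK = meanK, kR = kR,
      meanAlpha = meanAlpha, alphaR = alphaR, cvK = cvK, cvAlpha = cvAlpha,
      cvChi = cvChi, phi0 = phi0, mR = mR, chiRRange = as.numeric(chiRRange),
      nEnvironments = as.integer(nEnvironments), seed = as.integer(seed))
}

#' Result of an environment ensemble run
#'
#' @slot records per-environment data.frame with columns env_id, mu_per_min,
#'   phi_R, I_chi_k, I_phi_alpha, k_chi, alpha_phi, seed.
#' @slot proteome the (possibly mode-transformed) [ProteomeParams-class]
#'   shared by all environments.
#' @slot mode simulation mode used ("full", "no_degradation",
#'   "homogeneous_speed").
#' @slot seed master seed of the run.
#' @exportClass EnsembleResult
setClass("EnsembleResult",
  representation(records = "data.frame", proteome = "ProteomeParams",
                 mode = "character", seed = "integer"))

#' A synthetic multi-condition study with known ground truth
#'
#' Emulates the processed form of a ribosome-profiling + proteomics study:
#' per-condition gene tables (allocation count fractions, mass fractions,
#' translation speeds, degradation rates, lengths) and OD600 growth curves,
#' generated from a known proteome and index-targeted environments so every
#' downstream quantity has a retrievable truth.
#'
#' @slot proteome ground-truth [ProteomeParams-class].
#' @slot environments list of ground-truth [CellEnvironment-class] objects.
#' @slot states list of ground-truth [SteadyState-class] objects.
#' @slot tables list of per-condition gene tables (data.frames) with
#'   measurement noise applied.
#' @slot odCurves list of per-condition OD600 data.frames (time_min, od).
#' @slot schedule the per-condition index targets (data.frame IChiK,
#'   IPhiAlpha).
#' @slot noiseCV named list of measurement CVs per emitted quantity.
#' @slot seed master seed.
#' @exportClass SyntheticStudy
setClass("SyntheticStudy",
  representation(proteome = "ProteomeParams", environments = "list",
                 states = "list", tables = "list", odCurves = "list",
                 schedule = "data.frame", noiseCV = "list", seed = "integer"))
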