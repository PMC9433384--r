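#' Accessors for riboGrowthLaw objects
#'
#' Small read-only accessors: \code{nGenes}, \code{translationSpeeds},
#' \code{degradationRates}, \code{ribosomeMass}, \code{inactiveFraction},
#' \code{meanSpeed} / \code{meanDegradation} (arithmetic means over
#' non-ribosomal proteins), \code{allocations} / \code{chiR} /
#' \code{chiTilde} for environments, \code{growthRate}, \code{massFractions},
#' \code{phiR}, \code{phiTilde}, \code{weightedSpeedValue},
#' \code{weightedDegradationValue}, \code{allocationSpeedIndex},
#' \code{massDegradationIndex} for steady states, and
#' \code{curveCoefficients}, \code{confint95}, \code{fitRMSE},
#' \code{ensembleRecords}, \code{studyTables}, \code{groundTruth} for result
#' containers.
#'
#' @param object the object to access.
#' @return the slot value or derived quantity (see the generic's name).
#' @name accessors
NULL

#' @rdname accessors
setMethod("nGenes", "ProteomeParams", function(object) length(object@k))

#' @rdname accessors
setMethod("translationSpeeds", "ProteomeParams", function(object) object@k)

#' @rdname accessors
setMethod("degradationRates", "ProteomeParams", function(object) object@alpha)

#' @rdname accessors
setMethod("ribosomeMass", "ProteomeParams", function(object) object@mR)

#' @rdname accessors
setMethod("inactiveFraction", "ProteomeParams", function(object) object@phi0)

#' @rdname accessors
setMethod("meanSpeed", "ProteomeParams",
          function(object) mean(object@k[-1]))

#' @rdname accessors
setMethod("meanDegradation", "ProteomeParams",
          function(object) mean(object@alpha[-1]))

#' @rdname accessors
setMethod("allocations", "CellEnvironment", function(object) object@chi)

#' @rdname accessors
setMethod("chiR", "CellEnvironment", function(object) object@chi[1])

#' @rdname accessors
setMethod("chiTilde", "CellEnvironment", function(object) {
  cR <- object@chi[1]
  if (cR >= 1)
    stop("degenerate environment: chi_R = 1 leaves no non-ribosomal allocation")
  object@chi[-1] / (1 - cR)
})

#' @rdname accessors
setMethod("growthRate", "SteadyState", function(object) object@mu)

#' @rdname accessors
setMethod("massFractions", "SteadyState", function(object) object@phi)

#' @rdname accessors
setMethod("phiR", "SteadyState", function(object) object@phi[1])

#' @rdname accessors
setMethod("phiTilde", "SteadyState",
          function(object) object@phi[-1] / (1 - object@phi[1]))

#' @rdname accessors
setMethod("weightedSpeedValue", "SteadyState", function(object) object@kChi)

#' @rdname accessors
setMethod("weightedDegradationValue", "SteadyState",
          function(object) object@alphaPhi)

#' @rdname accessors
setMethod("allocationSpeedIndex", "SteadyState", function(object) object@IChiK)

#' @rdname accessors
setMethod("massDegradationIndex", "SteadyState",
          function(object) object@IPhiAlpha)

#' @rdname accessors
setMethod("curveCoefficients", "GrowthLawCoefficients",
          function(object) c(c1 = object@c1, c2 = object@c2, c3 = object@c3))

#' @rdname accessors
setMethod("curveCoefficients", "GrowthLawFit",
          function(object) object@coefficients)

#' @rdname accessors
setMethod("confint95", "GrowthLawFit", function(object) object@ci)

#' @rdname accessors
setMethod("fitRMSE", "GrowthLawFit", function(object) object@rmse)

#' @rdname accessors
setMethod("ensembleRecords", "EnsembleResult", function(object) object@records)

#' @rdname accessors
setMethod("studyTables", "SyntheticStudy", function(object) object@tables)

#' @rdname accessors
setMethod("groundTruth", "SyntheticStudy", function(object)
  list(proteome = object@proteome, environments = object@environments,
       states = object@states, schedule = object@schedule))

setMethod("show", "ProteomeParams", function(object) {
  cat("ProteomeParams with", length(object@k), "proteins\n")
  cat(sprintf("  k_R = %.4g Da/min, <k> = %.4g Da/min\n",
              object@k[1], mean(object@k[-1])))
  cat(sprintf("  alpha_R = %.4g /min, <alpha> = %.4g /min\n",
              object@alpha[1], mean(object@alpha[-1])))
  cat(sprintf("  m_R = %.4g Da, phi0 = %.3g\n", object@mR, object@phi0))
})

setMethod("show", "CellEnvironment", function(object) {
  cat("CellEnvironment over", length(object@chi), "proteins\n")
  cat(sprintf("  chi_R = %.4g\n", object@chi[1]))
})

setMethod("show", "SteadyState", function(object) {
  cat("SteadyState\n")
  cat(sprintf("  mu = %.6g /min (%.4g /h)%s\n", object@mu, object@mu * 60,
              if (object@negativeGrowth) "  [negative growth]" else ""))
  cat(sprintf("  phi_R = %.6g\n", object@phi[1]))
  cat(sprintf("  <k>_chi = %.6g Da/min, <alpha>_phi = %.6g /min\n",
              object@kChi, object@alphaPhi))
  cat(sprintf("  I_chi,k = %.4g, I_phi,alpha = %.4g\n",
              object@IChiK, object@IPhiAlpha))
})

setMethod("show", "GrowthLawCoefficients", function(object) {
  cat("GrowthLawCoefficients: phi_R = (mu + c1) / (c2 mu + c3)\n")
  cat(sprintf("  c1 = %.6g /min, c2 = %.6g, c3 = %.6g /min\n",
              object@c1, object@c2, object@c3))
  sh <- curveShape(object)
  cat(sprintf("  increasing: %s, convex: %s\n", sh$increasing, sh$convex))
})

setMethod("show", "GrowthLawFit", function(object) {
  cat("GrowthLawFit on", object@nObs, "points\n")
  est <- object@coefficients
  for (i in seq_along(est))
    cat(sprintf("  %s = %.6g  [95%% CI %.6g, %.6g]\n", names(est)[i], est[i],
                object@ci[i, 1], object@ci[i, 2]))
  cat(sprintf("  RMSE = %.4g\n", object@rmse))
})

setMethod("show", "EnsembleConfig", function(object) {
  cat("EnsembleConfig:", object@nGenes, "genes,",
      object@nEnvironments, "environments, seed", object@seed, "\n")
})

setMethod("show", "EnsembleResult", function(object) {
  cat("EnsembleResult (mode:", object@mode, ") with",
      nrow(object@records), "environments\n")
  cat(sprintf("  mu range [%.4g, %.4g] /min, phi_R range [%.4g, %.4g]\n",
              min(object@records$mu_per_min), max(object@records$mu_per_min),
              min(object@records$phi_R), max(object@records$phi_R)))
})

setMethod("show", "SyntheticStudy", function(object) {
  cat("SyntheticStudy:", nGenes(object@proteome), "genes,",
      length(object@states), "conditions, seed", object@seed, "\n")
})
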