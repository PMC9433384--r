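#' @rdname accessors
#' @export
setGeneric("nGenes", function(object) standardGeneric("nGenes"))

#' @rdname accessors
#' @export
setGeneric("translationSpeeds",
           function(object) standardGeneric("translationSpeeds"))

#' @rdname accessors
#' @export
setGeneric("degradationRates",
           function(object) standardGeneric("degradationRates"))

#' @rdname accessors
#' @export
setGeneric("ribosomeMass", function(object) standardGeneric("ribosomeMass"))

#' @rdname accessors
#' @export
setGeneric("inactiveFraction",
           function(object) standardGeneric("inactiveFraction"))

#' @rdname accessors
#' @export
setGeneric("meanSpeed", function(object) standardGeneric("meanSpeed"))

#' @rdname accessors
#' @export
setGeneric("meanDegradation",
           function(object) standardGeneric("meanDegradation"))

#' @rdname accessors
#' @export
setGeneric("allocations", function(object) standardGeneric("allocations"))

#' @rdname accessors
#' @export
setGeneric("chiR", function(object) standardGeneric("chiR"))

#' @rdname accessors
#' @export
setGeneric("chiTilde", function(object) standardGeneric("chiTilde"))

#' @rdname accessors
#' @export
setGeneric("growthRate", function(object) standardGeneric("growthRate"))

#' @rdname accessors
#' @export
setGeneric("massFractions", function(object) standardGeneric("massFractions"))

#' @rdname accessors
#' @export
setGeneric("phiR", function(object) standardGeneric("phiR"))

#' @rdname accessors
#' @export
setGeneric("phiTilde", function(object) standardGeneric("phiTilde"))

#' @rdname accessors
#' @export
setGeneric("weightedSpeedValue",
           function(object) standardGeneric("weightedSpeedValue"))

#' @rdname accessors
#' @export
setGeneric("weightedDegradationValue",
           function(object) standardGeneric("weightedDegradationValue"))

#' @rdname accessors
#' @export
setGeneric("allocationSpeedIndex",
           function(object) standardGeneric("allocationSpeedIndex"))

#' @rdname accessors
#' @export
setGeneric("massDegradationIndex",
           function(object) standardGeneric("massDegradationIndex"))

#' @rdname accessors
#' @export
setGeneric("curveCoefficients",
           function(object) standardGeneric("curveCoefficients"))

#' @rdname accessors
#' @export
setGeneric("confint95", function(object) standardGeneric("confint95"))

#' @rdname accessors
#' @export
setGeneric("fitRMSE", function(object) standardGeneric("fitRMSE"))

#' @rdname accessors
#' @export
setGeneric("ensembleRecords",
           function(object) standardGeneric("ensembleRecords"))

#' @rdname accessors
#' @export
setGeneric("studyTables", function(object) standardGeneric("studyTables"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
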