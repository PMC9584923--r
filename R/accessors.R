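# Accessor generics for the S4 containers.  Positions index residues 1-based,
# inclusive, throughout the package.

#' @rdname BackboneProfile-class
#' @param object a \code{BackboneProfile}, \code{TransferFunction} or
#'   \code{PPVModel}.
#' @export
setGeneric("profileAccession", function(object) standardGeneric("profileAccession"))
#' @rdname BackboneProfile-class
#' @export
setGeneric("profileLength", function(object) standardGeneric("profileLength"))
#' @rdname BackboneProfile-class
#' @export
setGeneric("startIntensity", function(object) standardGeneric("startIntensity"))
#' @rdname BackboneProfile-class
#' @export
setGeneric("stopIntensity", function(object) standardGeneric("stopIntensity"))
#' @rdname BackboneProfile-class
#' @export
setGeneric("coverageVector", function(object) standardGeneric("coverageVector"))
#' @rdname BackboneProfile-class
#' @export
setGeneric("startCount", function(object) standardGeneric("startCount"))
#' @rdname BackboneProfile-class
#' @export
setGeneric("stopCount", function(object) standardGeneric("stopCount"))
#' @rdname BackboneProfile-class
#' @export
setGeneric("amidatedStopIntensity", function(object) standardGeneric("amidatedStopIntensity"))
#' @rdname BackboneProfile-class
#' @export
setGeneric("acetylatedStartIntensity", function(object) standardGeneric("acetylatedStartIntensity"))

#' @rdname BackboneProfile-class
setMethod("profileAccession", "BackboneProfile", function(object) object@accession)
#' @rdname BackboneProfile-class
setMethod("profileLength", "BackboneProfile", function(object) object@length)
#' @rdname BackboneProfile-class
setMethod("startIntensity", "BackboneProfile", function(object) object@startIntensity)
#' @rdname BackboneProfile-class
setMethod("stopIntensity", "BackboneProfile", function(object) object@stopIntensity)
#' @rdname BackboneProfile-class
setMethod("coverageVector", "BackboneProfile", function(object) object@coverage)
#' @rdname BackboneProfile-class
setMethod("startCount", "BackboneProfile", function(object) object@startCount)
#' @rdname BackboneProfile-class
setMethod("stopCount", "BackboneProfile", function(object) object@stopCount)
#' @rdname BackboneProfile-class
setMethod("amidatedStopIntensity", "BackboneProfile", function(object) object@amidatedStopIntensity)
#' @rdname BackboneProfile-class
setMethod("acetylatedStartIntensity", "BackboneProfile", function(object) object@acetylatedStartIntensity)

#' @rdname TransferFunction-class
#' @param object a \code{TransferFunction}.
#' @export
setGeneric("transferCoefficients", function(object) standardGeneric("transferCoefficients"))
#' @rdname TransferFunction-class
setMethod("transferCoefficients", "TransferFunction",
    function(object) c(a = object@a, b = object@b))

#' @rdname PPVModel-class
#' @export
setGeneric("oofScores", function(object) standardGeneric("oofScores"))
#' @rdname PPVModel-class
#' @export
setGeneric("innerCoefficients", function(object) standardGeneric("innerCoefficients"))
#' @rdname PPVModel-class
#' @export
setGeneric("finalWeights", function(object) standardGeneric("finalWeights"))
#' @rdname PPVModel-class
#' @export
setGeneric("outerFoldAssignment", function(object) standardGeneric("outerFoldAssignment"))
#' @rdname PPVModel-class
#' @export
setGeneric("outerStandardization", function(object) standardGeneric("outerStandardization"))

#' @rdname PPVModel-class
setMethod("oofScores", "PPVModel", function(object) object@oofScores)
#' @rdname PPVModel-class
setMethod("innerCoefficients", "PPVModel", function(object) object@innerCoefs)
#' @rdname PPVModel-class
setMethod("finalWeights", "PPVModel", function(object) object@finalWeights)
#' @rdname PPVModel-class
setMethod("outerFoldAssignment", "PPVModel", function(object) object@outerFold)
#' @rdname PPVModel-class
setMethod("outerStandardization", "PPVModel",
    function(object) list(center = object@outerCenter,
                          scale = object@outerScale))
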