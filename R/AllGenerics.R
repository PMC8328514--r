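#' @rdname correctBaseline
#' @export
setGeneric("correctBaseline", function(chrom, ...)
  standardGeneric("correctBaseline"))

#' @rdname fitPeaks
#' @export
setGeneric("fitPeaks", function(chrom, ...) standardGeneric("fitPeaks"))

#' @rdname assignSpecies
#' @export
setGeneric("assignSpecies", function(fit, ...) standardGeneric("assignSpecies"))

#' @rdname computeLevels
#' @export
setGeneric("computeLevels", function(assignment, ...)
  standardGeneric("computeLevels"))

#' @rdname subtractBackground
#' @export
setGeneric("subtractBackground", function(profile, ...)
  standardGeneric("subtractBackground"))

#' @rdname quantifyBands
#' @export
setGeneric("quantifyBands", function(profile, ...)
  standardGeneric("quantifyBands"))

#' @rdname minComDistance
#' @export
setGeneric("minComDistance", function(config, ...)
  standardGeneric("minComDistance"))

#' @rdname detectDimer
#' @export
setGeneric("detectDimer", function(config, ...) standardGeneric("detectDimer"))

#' @rdname electrostaticContacts
#' @export
setGeneric("electrostaticContacts", function(config, ...)
  standardGeneric("electrostaticContacts"))

#' @rdname hydrogenBonds
#' @export
setGeneric("hydrogenBonds", function(config, ...)
  standardGeneric("hydrogenBonds"))

#' @rdname nonpolarContacts
#' @export
setGeneric("nonpolarContacts", function(config, ...)
  standardGeneric("nonpolarContacts"))

#' @rdname helixTilt
#' @export
setGeneric("helixTilt", function(protomer, ...) standardGeneric("helixTilt"))

#' @rdname interactingHelices
#' @export
setGeneric("interactingHelices", function(config, ...)
  standardGeneric("interactingHelices"))

#' @rdname classifyInterface
#' @export
setGeneric("classifyInterface", function(contacts, ...)
  standardGeneric("classifyInterface"))

#' @rdname meltDerivative
#' @export
setGeneric("meltDerivative", function(curve, ...)
  standardGeneric("meltDerivative"))

#' @rdname detectMeltEvents
#' @export
setGeneric("detectMeltEvents", function(curve, ...)
  standardGeneric("detectMeltEvents"))

#' @rdname classifyAggregation
#' @export
setGeneric("classifyAggregation", function(series, ...)
  standardGeneric("classifyAggregation"))

#' @rdname ionicStrength
#' @export
setGeneric("ionicStrength", function(buffer, ...)
  standardGeneric("ionicStrength"))
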