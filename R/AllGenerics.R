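## Generics. Accessors are preferred over direct slot access throughout.

#' @export
setGeneric("georef", function(x) standardGeneric("georef"))

#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @export
setGeneric("bandLabel", function(x) standardGeneric("bandLabel"))

#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @export
setGeneric("sceneBands", function(x) standardGeneric("sceneBands"))

#' @export
setGeneric("bathymetry", function(x) standardGeneric("bathymetry"))

#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @export
setGeneric("classMap", function(x) standardGeneric("classMap"))

#' @export
setGeneric("sampleFeatures", function(x) standardGeneric("sampleFeatures"))

#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @export
setGeneric("sampleLocations", function(x) standardGeneric("sampleLocations"))

#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))

#' @export
setGeneric("overallAccuracy", function(x) standardGeneric("overallAccuracy"))

#' @export
setGeneric("kappaIndex", function(x) standardGeneric("kappaIndex"))

#' @export
setGeneric("userAccuracy", function(x) standardGeneric("userAccuracy"))

#' @export
setGeneric("producerAccuracy",
           function(x) standardGeneric("producerAccuracy"))

#' @export
setGeneric("attenuationKd", function(x) standardGeneric("attenuationKd"))

#' @export
setGeneric("deepWaterRInf", function(x) standardGeneric("deepWaterRInf"))

#' @export
setGeneric("pixelCounts", function(x) standardGeneric("pixelCounts"))

#' @export
setGeneric("areaHa", function(x) standardGeneric("areaHa"))
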