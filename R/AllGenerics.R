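#' @rdname siteTable
#' @export
setGeneric("siteTable", function(x) standardGeneric("siteTable"))

#' @rdname zScores
#' @export
setGeneric("zScores", function(x) standardGeneric("zScores"))

#' @rdname noiseModel
#' @export
setGeneric("noiseModel", function(x) standardGeneric("noiseModel"))

#' @rdname gridGeometry
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname photostimTrace
#' @export
setGeneric("traceSamples", function(x) standardGeneric("traceSamples"))

#' Integrate baseline-subtracted synaptic charge over a window
#'
#' @param trace a [PhotostimTrace-class] (or numeric vector, with \code{dt}
#'   and \code{stimOnset} supplied).
#' @param ... passed to methods.
#' @export
setGeneric("integrateCharge",
           function(trace, ...) standardGeneric("integrateCharge"))

#' @rdname estimateNoise
#' @export
setGeneric("estimateNoise",
           function(traces, ...) standardGeneric("estimateNoise"))

#' @rdname removeDirectCurrent
#' @export
setGeneric("removeDirectCurrent",
           function(trace, ...) standardGeneric("removeDirectCurrent"))

#' @rdname detectEvents
#' @export
setGeneric("detectEvents",
           function(trace, ...) standardGeneric("detectEvents"))

#' @rdname classifySites
#' @export
setGeneric("classifySites",
           function(map, ...) standardGeneric("classifySites"))

#' @rdname maxProject
#' @export
setGeneric("maxProject", function(map) standardGeneric("maxProject"))

#' @rdname toPattern
#' @export
setGeneric("toPattern", function(x, ...) standardGeneric("toPattern"))

#' @rdname patternCorrelation
#' @export
setGeneric("patternCorrelation",
           function(p1, p2, ...) standardGeneric("patternCorrelation"))

#' @rdname clusterIds
#' @export
setGeneric("clusterIds", function(x) standardGeneric("clusterIds"))

#' Accessors for pattern coordinates and values
#'
#' @param x a [MediolateralPattern-class].
#' @return \code{patternPositions}: the um-from-midline support;
#'   \code{patternValues}: the (smoothed) Z values on that support.
#' @name pattern-accessors
#' @export
setGeneric("patternPositions",
           function(x) standardGeneric("patternPositions"))

#' @rdname pattern-accessors
#' @export
setGeneric("patternValues", function(x) standardGeneric("patternValues"))
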