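#' @include utils.R
NULL

#' @export
setGeneric("vesselId", function(x) standardGeneric("vesselId"))

#' @export
setGeneric("phase", function(x) standardGeneric("phase"))

#' @export
setGeneric("tracePositions", function(x) standardGeneric("tracePositions"))

#' @export
setGeneric("qfrValues", function(x) standardGeneric("qfrValues"))

#' @export
setGeneric("totalVesselLength", function(x) standardGeneric("totalVesselLength"))

#' @export
setGeneric("resampleTrace", function(trace, stepMm) standardGeneric("resampleTrace"))

#' @export
setGeneric("monotoneEnvelope", function(trace) standardGeneric("monotoneEnvelope"))

#' @export
setGeneric("indexQFR", function(trace, positionMm) standardGeneric("indexQFR"))

#' @export
setGeneric("deltaQFRVessel", function(trace) standardGeneric("deltaQFRVessel"))

#' @export
setGeneric("tracePre", function(x) standardGeneric("tracePre"))

#' @export
setGeneric("tracePost", function(x) standardGeneric("tracePost"))

#' @export
setGeneric("lesionComponents", function(x) standardGeneric("lesionComponents"))

#' @export
setGeneric("truePattern", function(x) standardGeneric("truePattern"))

#' @export
setGeneric("postQFR", function(x) standardGeneric("postQFR"))

#' @export
setGeneric("stentedIntervals", function(x) standardGeneric("stentedIntervals"))

#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))

#' @export
setGeneric("nVessels", function(x) standardGeneric("nVessels"))

#' @export
setGeneric("vessels", function(x) standardGeneric("vessels"))

#' @export
setGeneric("cohortManifest", function(x) standardGeneric("cohortManifest"))
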