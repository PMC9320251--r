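#' @include AllClasses.R
NULL

#' Accessors for walkHRV signal containers
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x a walkHRV S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("rrIntervals", function(x) standardGeneric("rrIntervals"))

#' @rdname accessors
#' @export
setGeneric("beatTimes", function(x) standardGeneric("beatTimes"))

#' @rdname accessors
#' @export
setGeneric("beatAnnotations", function(x) standardGeneric("beatAnnotations"))

#' @rdname accessors
#' @export
setGeneric("phaseLabels", function(x) standardGeneric("phaseLabels"))

#' @rdname accessors
#' @export
setGeneric("segmentation", function(x) standardGeneric("segmentation"))

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("ecgSamples", function(x) standardGeneric("ecgSamples"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("truthBeatTimes", function(x) standardGeneric("truthBeatTimes"))

#' @rdname accessors
#' @export
setGeneric("rTimes", function(x) standardGeneric("rTimes"))

#' @rdname accessors
#' @export
setGeneric("rAmplitudes", function(x) standardGeneric("rAmplitudes"))
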