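#' @include AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("rrIntervals", "RRSeries", function(x) x@intervals)

#' @rdname accessors
#' @export
setMethod("beatTimes", "RRSeries", function(x) x@beatTimes)

#' @rdname accessors
#' @export
setMethod("beatAnnotations", "RRSeries", function(x) x@annotations)

#' @rdname accessors
#' @export
setMethod("phaseLabels", "RRSeries", function(x) x@phases)

#' @rdname accessors
#' @export
setMethod("segmentation", "RRSeries", function(x) x@segmentation)

#' @rdname accessors
#' @export
setMethod("subjectId", "RRSeries", function(x) x@subjectId)

#' @rdname accessors
#' @export
setMethod("subjectId", "ECGRecord", function(x) x@subjectId)

#' @rdname accessors
#' @export
setMethod("subjectId", "BeatSeries", function(x) x@subjectId)

#' @rdname accessors
#' @export
setMethod("ecgSamples", "ECGRecord", function(x) x@samples)

#' @rdname accessors
#' @export
setMethod("samplingRate", "ECGRecord", function(x) x@samplingRate)

#' @rdname accessors
#' @export
setMethod("truthBeatTimes", "ECGRecord", function(x) x@truthBeatTimes)

#' @rdname accessors
#' @export
setMethod("rTimes", "BeatSeries", function(x) x@rTimes)

#' @rdname accessors
#' @export
setMethod("rAmplitudes", "BeatSeries", function(x) x@rAmplitudes)

#' Number of intervals / beats / samples
#'
#' `length()` of an `RRSeries` is its number of intervals, of a `BeatSeries`
#' its number of detected beats, and of an `ECGRecord` its number of samples.
#'
#' @param x a walkHRV S4 object.
#' @name length-methods
NULL

#' @rdname length-methods
#' @export
setMethod("length", "RRSeries", function(x) length(x@intervals))

#' @rdname length-methods
#' @export
setMethod("length", "BeatSeries", function(x) length(x@rTimes))

#' @rdname length-methods
#' @export
setMethod("length", "ECGRecord", function(x) length(x@samples))

setMethod("show", "RRSeries", function(object) {
  n <- length(object@intervals)
  cat(sprintf("RRSeries: %d intervals", n))
  if (!is.na(object@subjectId)) cat(sprintf(" [subject %s]", object@subjectId))
  cat("\n")
  if (n) {
    cat(sprintf("  span: %.1f s, mean RR %.1f ms\n",
                diff(range(object@beatTimes)), mean(object@intervals)))
    tab <- table(object@annotations)
    cat("  annotations:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    if (any(!is.na(object@phases))) {
      pt <- table(object@phases, useNA = "no")
      cat("  phases:",
          paste(sprintf("%s=%d", names(pt), pt), collapse = ", "), "\n")
    }
  }
  invisible(object)
})

setMethod("show", "BeatSeries", function(object) {
  cat(sprintf("BeatSeries: %d beats", length(object@rTimes)))
  if (!is.na(object@subjectId)) cat(sprintf(" [subject %s]", object@subjectId))
  cat("\n")
  if (length(object@rTimes) > 1)
    cat(sprintf("  span: %.1f s, mean rate %.1f bpm\n",
                diff(range(object@rTimes)),
                60 * (length(object@rTimes) - 1) /
                  diff(range(object@rTimes))))
  invisible(object)
})

setMethod("show", "ECGRecord", function(object) {
  cat(sprintf("ECGRecord: %d samples at %g Hz (%.1f s)",
              length(object@samples), object@samplingRate,
              length(object@samples) / object@samplingRate))
  if (!is.na(object@subjectId)) cat(sprintf(" [subject %s]", object@subjectId))
  cat("\n")
  if (length(object@truthBeatTimes))
    cat(sprintf("  %d ground-truth beat times retained\n",
                length(object@truthBeatTimes)))
  invisible(object)
})

setMethod("show", "PhaseSegmentation", function(object) {
  cat(sprintf(
    "PhaseSegmentation: baseline [%g, %g) s, walking [%g, %g) s, recovery [%g, %g] s\n",
    object@tBaselineStart, object@tWalkStart, object@tWalkStart,
    object@tWalkEnd, object@tWalkEnd, object@tRecoveryEnd))
  invisible(object)
})

setMethod("show", "ROCCurve", function(object) {
  ineq <- if (object@orientation == "positive_if_greater") ">=" else "<="
  cat(sprintf("ROCCurve for %s (%d points): positive (%s) if value %s cutoff\n",
              object@indexName, length(object@thresholds),
              object@positiveLabel, ineq))
  cat(sprintf("  %d positive, %d negative subjects\n",
              sum(object@labels), sum(!object@labels)))
  invisible(object)
})
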