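#' @import methods
NULL

.ANNOTATION_LEVELS <- c("normal", "ectopic", "artifact", "corrected")
.PHASE_LEVELS <- c("baseline", "walking", "recovery")

#' Single-channel ECG record
#'
#' Container for a uniformly sampled single-lead ECG trace. When the record
#' was produced by [generateEcgFromBeats()], the ground-truth beat times used
#' to build it are retained in `truthBeatTimes` so that detector performance
#' can be scored exactly.
#'
#' @slot samples numeric vector of amplitudes (mV).
#' @slot samplingRate sampling frequency in Hz.
#' @slot subjectId subject identifier.
#' @slot truthBeatTimes numeric vector of known beat times (s), or
#'   `numeric(0)` for real recordings.
#' @export
setClass("ECGRecord",
  representation(
    samples = "numeric",
    samplingRate = "numeric",
    subjectId = "character",
    truthBeatTimes = "numeric"
  ),
  prototype(
    samples = numeric(0), samplingRate = 250,
    subjectId = NA_character_, truthBeatTimes = numeric(0)
  )
)

setValidity("ECGRecord", function(object) {
  msg <- character(0)
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0) {
    msg <- c(msg, "samplingRate must be a single positive number")
  }
  if (anyNA(object@samples)) msg <- c(msg, "samples must not contain NA")
  if (length(object@truthBeatTimes) > 1L &&
      any(diff(object@truthBeatTimes) <= 0)) {
    msg <- c(msg, "truthBeatTimes must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

#' Detected R-peak series
#'
#' R-wave occurrence times and amplitudes as returned by [detectRPeaks()].
#'
#' @slot rTimes numeric, strictly increasing peak times (s from record start).
#' @slot rAmplitudes numeric, raw-signal amplitude at each peak (mV).
#' @slot subjectId subject identifier.
#' @export
setClass("BeatSeries",
  representation(
    rTimes = "numeric",
    rAmplitudes = "numeric",
    subjectId = "character"
  ),
  prototype(rTimes = numeric(0), rAmplitudes = numeric(0),
            subjectId = NA_character_)
)

setValidity("BeatSeries", function(object) {
  msg <- character(0)
  if (length(object@rTimes) != length(object@rAmplitudes))
    msg <- c(msg, "rTimes and rAmplitudes must have equal length")
  if (length(object@rTimes) > 1L && any(diff(object@rTimes) <= 0))
    msg <- c(msg, "rTimes must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Walking-test phase boundaries
#'
#' Protocol timestamps (seconds from record start) delimiting the standing
#' baseline, the 160 m walk and the standing recovery.
#'
#' @slot tBaselineStart start of the baseline rest (s).
#' @slot tWalkStart walk onset (s).
#' @slot tWalkEnd end of the walk (s).
#' @slot tRecoveryEnd end of the recovery rest (s).
#' @export
setClass("PhaseSegmentation",
  representation(
    tBaselineStart = "numeric",
    tWalkStart = "numeric",
    tWalkEnd = "numeric",
    tRecoveryEnd = "numeric"
  )
)

setValidity("PhaseSegmentation", function(object) {
  b <- c(object@tBaselineStart, object@tWalkStart, object@tWalkEnd,
         object@tRecoveryEnd)
  if (length(b) != 4L || anyNA(b) || any(!is.finite(b)))
    return("all four boundaries must be single finite numbers")
  if (any(diff(b) <= 0))
    return("boundaries must be strictly increasing")
  TRUE
})

#' RR-interval series
#'
#' Beat-to-beat interval sequence with per-interval annotations and optional
#' phase labels. `beatTimes[i]` is the time (s) at which interval `i` ends;
#' `intervals[i]` is its duration in milliseconds.
#'
#' @slot intervals numeric, interval durations (ms), all positive.
#' @slot beatTimes numeric, strictly increasing interval end times (s).
#' @slot annotations character, one of `"normal"`, `"ectopic"`, `"artifact"`,
#'   `"corrected"` per interval.
#' @slot phases character, one of `"baseline"`, `"walking"`, `"recovery"` or
#'   `NA` per interval (empty until [segmentPhases()] is applied).
#' @slot segmentation a [PhaseSegmentation-class] or `NULL`.
#' @slot subjectId subject identifier.
#' @export
setClass("RRSeries",
  representation(
    intervals = "numeric",
    beatTimes = "numeric",
    annotations = "character",
    phases = "character",
    segmentation = "ANY",
    subjectId = "character"
  ),
  prototype(
    intervals = numeric(0), beatTimes = numeric(0),
    annotations = character(0), phases = character(0),
    segmentation = NULL, subjectId = NA_character_
  )
)

setValidity("RRSeries", function(object) {
  msg <- character(0)
  n <- length(object@intervals)
  if (length(object@beatTimes) != n)
    msg <- c(msg, "intervals and beatTimes must have equal length")
  if (length(object@annotations) != n)
    msg <- c(msg, "annotations must have one entry per interval")
  if (n && (anyNA(object@intervals) || any(object@intervals <= 0)))
    msg <- c(msg, "all intervals must be positive and non-missing")
  if (n > 1L && any(diff(object@beatTimes) <= 0))
    msg <- c(msg, "beatTimes must be strictly increasing")
  if (length(object@annotations) &&
      !all(object@annotations %in% .ANNOTATION_LEVELS))
    msg <- c(msg, sprintf("annotations must be one of: %s",
                          paste(.ANNOTATION_LEVELS, collapse = ", ")))
  if (length(object@phases) &&
      !all(object@phases %in% c(.PHASE_LEVELS, NA_character_)))
    msg <- c(msg, sprintf("phases must be NA or one of: %s",
                          paste(.PHASE_LEVELS, collapse = ", ")))
  if (!is.null(object@segmentation) && !is(object@segmentation,
                                           "PhaseSegmentation"))
    msg <- c(msg, "segmentation must be NULL or a PhaseSegmentation")
  if (length(msg)) msg else TRUE
})

#' Receiver-operating-characteristic curve
#'
#' The full ROC path of a candidate frailty biomarker, including the infinite
#' threshold sentinels so that (0,0) and (1,1) are always on the curve. The
#' classification rule is non-strict on the positive side: with orientation
#' `"positive_if_greater"` a subject is called positive when
#' `value >= threshold`, with `"positive_if_less"` when `value <= threshold`.
#'
#' @slot thresholds numeric, candidate cut-offs (index units) incl. +/-Inf.
#' @slot tpr sensitivity at each threshold.
#' @slot fpr 1 - specificity at each threshold.
#' @slot orientation `"positive_if_greater"` or `"positive_if_less"`.
#' @slot scores the score values used (missing values removed).
#' @slot labels logical, `TRUE` for the positive (frail) class.
#' @slot indexName name of the index scored.
#' @slot positiveLabel label of the positive class.
#' @export
setClass("ROCCurve",
  representation(
    thresholds = "numeric",
    tpr = "numeric",
    fpr = "numeric",
    orientation = "character",
    scores = "numeric",
    labels = "logical",
    indexName = "character",
    positiveLabel = "character"
  )
)

setValidity("ROCCurve", function(object) {
  msg <- character(0)
  k <- length(object@thresholds)
  if (length(object@tpr) != k || length(object@fpr) != k)
    msg <- c(msg, "thresholds, tpr and fpr must have equal length")
  if (!object@orientation %in% c("positive_if_greater", "positive_if_less"))
    msg <- c(msg, "invalid orientation")
  if (k) {
    if (any(object@tpr < -1e-12) || any(object@tpr > 1 + 1e-12) ||
        any(object@fpr < -1e-12) || any(object@fpr > 1 + 1e-12))
      msg <- c(msg, "tpr and fpr must lie in [0, 1]")
  }
  if (length(object@scores) != length(object@labels))
    msg <- c(msg, "scores and labels must have equal length")
  if (length(msg)) msg else TRUE
})

# ---- constructors ---------------------------------------------------------

#' Construct an ECGRecord
#'
#' @param samples numeric amplitudes in mV.
#' @param samplingRate sampling frequency in Hz.
#' @param subjectId subject identifier.
#' @param truthBeatTimes known beat times (s), if any.
#' @return an [ECGRecord-class] object.
#' @export
ECGRecord <- function(samples, samplingRate, subjectId = NA_character_,
                      truthBeatTimes = numeric(0)) {
  new("ECGRecord", samples = as.numeric(samples),
      samplingRate = as.numeric(samplingRate),
      subjectId = as.character(subjectId),
      truthBeatTimes = as.numeric(truthBeatTimes))
}

#' Construct a BeatSeries
#'
#' @param rTimes strictly increasing peak times (s).
#' @param rAmplitudes peak amplitudes (mV); recycled NA if missing.
#' @param subjectId subject identifier.
#' @return a [BeatSeries-class] object.
#' @export
BeatSeries <- function(rTimes, rAmplitudes = rep(NA_real_, length(rTimes)),
                       subjectId = NA_character_) {
  new("BeatSeries", rTimes = as.numeric(rTimes),
      rAmplitudes = as.numeric(rAmplitudes),
      subjectId = as.character(subjectId))
}

#' Construct a PhaseSegmentation
#'
#' The protocol targets 5-min (300 s) baseline and recovery rests; spans
#' shorter than 240 s raise a warning because 5-min HRV indices become
#' unreliable on shorter segments.
#'
#' @param tWalkStart walk onset (s).
#' @param tWalkEnd walk end (s).
#' @param tBaselineStart baseline start (s), default 0.
#' @param tRecoveryEnd recovery end (s), default `tWalkEnd + 300`.
#' @return a [PhaseSegmentation-class] object.
#' @export
PhaseSegmentation <- function(tWalkStart, tWalkEnd, tBaselineStart = 0,
                              tRecoveryEnd = tWalkEnd + 300) {
  obj <- new("PhaseSegmentation",
             tBaselineStart = as.numeric(tBaselineStart),
             tWalkStart = as.numeric(tWalkStart),
             tWalkEnd = as.numeric(tWalkEnd),
             tRecoveryEnd = as.numeric(tRecoveryEnd))
  base <- obj@tWalkStart - obj@tBaselineStart
  rec <- obj@tRecoveryEnd - obj@tWalkEnd
  if (base < 240 || rec < 240)
    warning("baseline or recovery span is shorter than 240 s; ",
            "5-min HRV indices will be unreliable")
  obj
}

#' Construct an RRSeries
#'
#' @param intervals interval durations in ms.
#' @param beatTimes interval end times in s; defaults to the cumulative sum
#'   of the intervals.
#' @param annotations per-interval labels; default all `"normal"`.
#' @param phases per-interval phase labels; default unset.
#' @param segmentation optional [PhaseSegmentation-class].
#' @param subjectId subject identifier.
#' @return an [RRSeries-class] object.
#' @export
RRSeries <- function(intervals, beatTimes = cumsum(intervals) / 1000,
                     annotations = rep("normal", length(intervals)),
                     phases = rep(NA_character_, length(intervals)),
                     segmentation = NULL, subjectId = NA_character_) {
  new("RRSeries", intervals = as.numeric(intervals),
      beatTimes = as.numeric(beatTimes),
      annotations = as.character(annotations),
      phases = as.character(phases),
      segmentation = segmentation,
      subjectId = as.character(subjectId))
}
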