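#' Split an RR record into protocol phases
#'
#' Each interval is assigned to the phase containing its end time; an
#' interval whose end time falls exactly on a boundary goes to the later
#' phase (walk-onset effects belong to walking). Returns the three phase
#' segments as separate series.
#'
#' @param rr an [RRSeries-class].
#' @param seg a [PhaseSegmentation-class]; defaults to the one attached to
#'   `rr`.
#' @return named list of [RRSeries-class]: `baseline`, `walking`,
#'   `recovery`.
#' @export
segmentPhases <- function(rr, seg = segmentation(rr)) {
  .stopIfNot(is(rr, "RRSeries"), "rr must be an RRSeries")
  .stopIfNot(is(seg, "PhaseSegmentation"),
             "no segmentation attached and none supplied")
  t <- rr@beatTimes
  slack <- max(rr@intervals) / 1000  # a boundary may fall inside the last beat
  .stopIfNot(seg@tBaselineStart >= t[1] - rr@intervals[1] / 1000 - slack &&
               seg@tRecoveryEnd <= t[length(t)] + slack,
             "segmentation extends outside the recorded span")
  ph <- .assignPhases(t, seg)
  rr@phases <- ph
  rr@segmentation <- seg
  out <- lapply(.PHASE_LEVELS, function(p) {
    idx <- which(!is.na(ph) & ph == p)
    if (!length(idx))
      stop(sprintf("phase '%s' contains no intervals", p), call. = FALSE)
    new("RRSeries", intervals = rr@intervals[idx],
        beatTimes = t[idx], annotations = rr@annotations[idx],
        phases = ph[idx], segmentation = seg, subjectId = rr@subjectId)
  })
  names(out) <- .PHASE_LEVELS
  out
}

#' Instantaneous heart-rate curve
#'
#' `HR(t_i) = 60000 / RR_i` at the interval end times, optionally smoothed
#' by a centered moving average over a time window (default 10 s);
#' beat-to-beat maxima are noise-dominated, so the time-to-maximum
#' statistic is located on the smoothed curve. A zero window returns the
#' raw curve.
#'
#' @param rr an [RRSeries-class] segment.
#' @param smoothWindowS moving-average window in seconds (>= 0).
#' @return data.frame with `time` (s) and `hr` (bpm).
#' @export
instantaneousHr <- function(rr, smoothWindowS = 10) {
  .stopIfNot(is(rr, "RRSeries"), "rr must be an RRSeries")
  .stopIfNot(length(rr) >= 1, "empty segment")
  .stopIfNot(.isScalar(smoothWindowS) && smoothWindowS >= 0,
             "smoothWindowS must be non-negative")
  hr <- 60000 / rr@intervals
  data.frame(time = rr@beatTimes,
             hr = .movingAverageTime(rr@beatTimes, hr, smoothWindowS))
}

#' Time to maximum HR and maximal HR during the walk
#'
#' `hrMax` is the maximum of the (smoothed) walking-phase HR curve;
#' `deltaT` is the time from walk onset to its first attainment (ties
#' broken to the earliest).
#'
#' @param hrCurve data.frame from [instantaneousHr()] on the walking
#'   segment.
#' @param tWalkStart walk onset time (s), the zero of the delta-t clock.
#' @return list with `deltaT` (s) and `hrMax` (bpm).
#' @export
computeDeltaTHrMax <- function(hrCurve, tWalkStart) {
  .stopIfNot(is.data.frame(hrCurve) && nrow(hrCurve) >= 1 &&
               all(c("time", "hr") %in% names(hrCurve)),
             "hrCurve must be a non-empty data.frame with time and hr")
  .stopIfNot(.isScalar(tWalkStart), "tWalkStart must be a number")
  i <- which.max(hrCurve$hr)
  list(deltaT = max(0, hrCurve$time[i] - tWalkStart),
       hrMax = hrCurve$hr[i])
}

#' Velocity of the HR response
#'
#' `vResp = hrMax / deltaT` in bpm/s. A zero `deltaT` (maximum attained at
#' walk onset) yields a missing value flagged as an instantaneous response.
#'
#' @param deltaT time to maximum HR (s, >= 0).
#' @param hrMax maximal HR (bpm, >= 0).
#' @return list with `vResp` (bpm/s or NA) and `instantaneous` (logical).
#' @export
computeVresp <- function(deltaT, hrMax) {
  .stopIfNot(.isScalar(deltaT) && deltaT >= 0, "deltaT must be >= 0")
  .stopIfNot(.isScalar(hrMax) && hrMax >= 0, "hrMax must be >= 0")
  if (deltaT == 0)
    return(list(vResp = NA_real_, instantaneous = TRUE))
  list(vResp = hrMax / deltaT, instantaneous = FALSE)
}

#' Percentage HR change between two phases
#'
#' `100 * (hrA - hrB) / hrB`, the chronotropic-response measure applied to
#' (walking, baseline), (recovery, walking) and (recovery, baseline).
#'
#' @param hrPhaseA mean HR of the compared phase (bpm).
#' @param hrPhaseB mean HR of the reference phase (bpm, > 0).
#' @return percentage change.
#' @export
computeDeltaHr <- function(hrPhaseA, hrPhaseB) {
  .stopIfNot(.isScalar(hrPhaseA), "hrPhaseA must be a number")
  .stopIfNot(.isScalar(hrPhaseB) && hrPhaseB > 0,
             "reference HR must be positive")
  100 * (hrPhaseA - hrPhaseB) / hrPhaseB
}

#' Full chronotropic-response record for one subject
#'
#' Segments the record, computes phase mean HRs (`60000 / mean(RR)` per
#' phase), locates the walking-phase maximum on the smoothed HR curve, and
#' returns the response statistics: `delta_t`, `hr_max`, `v_resp` and the
#' three percentage changes `dhr_wb` (walking vs baseline), `dhr_rw`
#' (recovery vs walking) and `dhr_rb` (recovery vs baseline).
#'
#' @param rr an [RRSeries-class] with (or given) a segmentation.
#' @param seg a [PhaseSegmentation-class]; defaults to the attached one.
#' @param settings an [analysisSettings()] list (uses `smoothWindowS`).
#' @param walkingHr `"mean"` (default) or `"max"`: which walking-phase HR
#'   enters the walking-vs-baseline percentage change.
#' @return one-row data.frame.
#' @export
computeResponseIndices <- function(rr, seg = segmentation(rr),
                                   settings = analysisSettings(),
                                   walkingHr = c("mean", "max")) {
  walkingHr <- match.arg(walkingHr)
  phases <- segmentPhases(rr, seg)
  phaseMeanHr <- vapply(phases, function(p) 60000 / mean(p@intervals),
                        numeric(1))
  curve <- instantaneousHr(phases$walking, settings$smoothWindowS)
  dm <- computeDeltaTHrMax(curve, seg@tWalkStart)
  vr <- computeVresp(dm$deltaT, dm$hrMax)
  hrWalk <- if (walkingHr == "mean") phaseMeanHr[["walking"]] else dm$hrMax
  data.frame(
    delta_t = dm$deltaT,
    hr_max = dm$hrMax,
    v_resp = vr$vResp,
    dhr_wb = computeDeltaHr(hrWalk, phaseMeanHr[["baseline"]]),
    dhr_rw = computeDeltaHr(phaseMeanHr[["recovery"]], phaseMeanHr[["walking"]]),
    dhr_rb = computeDeltaHr(phaseMeanHr[["recovery"]], phaseMeanHr[["baseline"]]))
}
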