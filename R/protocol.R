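#' Walking-test protocol constants
#'
#' The study protocol: 5 min of standing rest (baseline), a 160 m walk at a
#' self-selected pace, and 5 min of standing rest (recovery). 160 m roughly
#' matches the validated 3-min walking test, because older adults walk at an
#' average gait speed of 0.89 m/s, and 180 s at that speed covers 160.2 m
#' (see [walkingDistance()]).
#'
#' @return a list with elements `baselineS` (300), `recoveryS` (300),
#'   `distanceM` (160), `referenceGaitSpeedMs` (0.89) and
#'   `referenceDurationS` (180).
#' @export
walkTestProtocol <- function() {
  list(baselineS = 300, recoveryS = 300, distanceM = 160,
       referenceGaitSpeedMs = 0.89, referenceDurationS = 180)
}

#' Distance covered at a given gait speed
#'
#' Convenience arithmetic used to relate the fixed 160 m distance to a timed
#' walking test: `durationS * gaitSpeedMs` metres.
#'
#' @param durationS walk duration in seconds.
#' @param gaitSpeedMs gait speed in m/s.
#' @return distance in metres.
#' @examples
#' walkingDistance(180, 0.89)  # 160.2 m, the 3-min-test equivalence
#' @export
walkingDistance <- function(durationS = walkTestProtocol()$referenceDurationS,
                            gaitSpeedMs = walkTestProtocol()$referenceGaitSpeedMs) {
  .stopIfNot(.isScalar(durationS) && durationS > 0,
             "durationS must be a positive number")
  .stopIfNot(.isScalar(gaitSpeedMs) && gaitSpeedMs > 0,
             "gaitSpeedMs must be a positive number")
  durationS * gaitSpeedMs
}
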