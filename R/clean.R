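.PHYSIO_GATE_MS <- c(250, 3000)

#' Flag ectopic beats and artifacts in an RR series
#'
#' Deterministic surrogate for visual inspection: interval `i` is flagged
#' `"artifact"` when it deviates from the median of its 11-interval local
#' window by more than `relThreshold` times that median, or when it falls
#' outside the 250-3000 ms physiologic gate. Other annotations are left
#' untouched. Series shorter than the local window fall back to the global
#' median (with a message).
#'
#' @param rr an [RRSeries-class].
#' @param relThreshold relative deviation threshold in (0, 1); default 0.25.
#' @return the [RRSeries-class] with updated annotations.
#' @export
flagAnomalousIntervals <- function(rr, relThreshold = 0.25) {
  .stopIfNot(is(rr, "RRSeries"), "rr must be an RRSeries")
  .stopIfNot(.isScalar(relThreshold) && relThreshold > 0 && relThreshold < 1,
             "relThreshold must be in (0, 1)")
  n <- length(rr)
  .stopIfNot(n >= 1, "empty RR series")
  v <- rr@intervals
  if (n < 11L) {
    message("series shorter than the 11-interval window; using global median")
    med <- rep(median(v), n)
  } else {
    med <- stats::runmed(v, k = 11L, endrule = "median")
  }
  bad <- abs(v - med) > relThreshold * med |
    v < .PHYSIO_GATE_MS[1] | v > .PHYSIO_GATE_MS[2]
  ann <- rr@annotations
  ann[bad & ann == "normal"] <- "artifact"
  rr@annotations <- ann
  validObject(rr)
  rr
}

#' Apply the artifact exclusion rule
#'
#' A recording is excluded from HRV analysis when more than `maxFraction`
#' (default 5%) of its intervals are flagged as ectopic or artifact. The
#' inequality is strict: a recording with exactly 5% flagged intervals is
#' kept.
#'
#' @param rr an [RRSeries-class] with populated annotations.
#' @param maxFraction maximum tolerated flagged fraction; default 0.05.
#' @return a list with `include` (logical), `fraction`, `nFlagged`, `n`.
#' @export
applyExclusionRule <- function(rr, maxFraction = 0.05) {
  .stopIfNot(is(rr, "RRSeries"), "rr must be an RRSeries")
  .stopIfNot(length(rr) >= 1, "empty RR series")
  .stopIfNot(.isScalar(maxFraction) && maxFraction >= 0,
             "maxFraction must be a non-negative number")
  flagged <- sum(rr@annotations %in% c("ectopic", "artifact"))
  frac <- flagged / length(rr)
  list(include = frac <= maxFraction, fraction = frac,
       nFlagged = flagged, n = length(rr))
}

#' Correct flagged intervals by cubic-spline interpolation
#'
#' Each flagged (`"ectopic"`/`"artifact"`) interval value is replaced by a
#' natural cubic spline fitted through the unflagged intervals as a function
#' of beat time, and re-annotated `"corrected"`. Runs of more than 5
#' consecutive flagged intervals are refused (left as-is, with a warning):
#' interpolation over long gaps would invent physiology. Beat times are not
#' moved; only interval values change, so `"normal"` intervals are returned
#' bitwise identical.
#'
#' @param rr an [RRSeries-class].
#' @param maxRun longest correctable run of consecutive flagged intervals.
#' @return the corrected [RRSeries-class].
#' @export
correctIntervals <- function(rr, maxRun = 5L) {
  .stopIfNot(is(rr, "RRSeries"), "rr must be an RRSeries")
  flaggedIdx <- which(rr@annotations %in% c("ectopic", "artifact"))
  if (!length(flaggedIdx)) return(rr)
  runs <- split(flaggedIdx, cumsum(c(1, diff(flaggedIdx) != 1)))
  fixable <- unlist(runs[vapply(runs, length, integer(1)) <= maxRun],
                    use.names = FALSE)
  refused <- setdiff(flaggedIdx, fixable)
  if (length(refused))
    warning(sprintf(
      "%d flagged interval(s) in runs longer than %d left uncorrected",
      length(refused), maxRun))
  if (!length(fixable)) return(rr)
  good <- setdiff(seq_len(length(rr)), flaggedIdx)
  .stopIfNot(length(good) >= 4,
             "too few clean intervals to support spline correction")
  sf <- splinefun(rr@beatTimes[good], rr@intervals[good], method = "natural")
  v <- rr@intervals
  v[fixable] <- pmax(sf(rr@beatTimes[fixable]), 1)
  rr@intervals <- v
  ann <- rr@annotations
  ann[fixable] <- "corrected"
  rr@annotations <- ann
  validObject(rr)
  rr
}
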