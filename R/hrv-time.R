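#' HRV analysis settings
#'
#' Tunable parameters of the HRV computations, with the package defaults:
#' tachogram resampling at 4 Hz (resolves the 0.4 Hz HF edge with margin),
#' linear detrending, 64 s Hann Welch windows with 50% overlap (>= 4
#' averages on a 5-min segment while still resolving 0.04 Hz), LF band
#' 0.04-0.15 Hz, HF band 0.15-0.4 Hz, entropy embedding dimension m = 2
#' with tolerance r = 0.2 x SD, and DFA box sizes 4-11 beats.
#'
#' @param resampleRate tachogram sampling rate, Hz.
#' @param detrend `"linear"` or `"none"`.
#' @param welchWindowS Welch segment length, s.
#' @param welchOverlap Welch segment overlap fraction in `[0, 1)`.
#' @param lfBand,hfBand length-2 numeric band limits in Hz; must be ordered
#'   and non-overlapping.
#' @param entropyM embedding dimension for ApEn/SampEn.
#' @param entropyRFactor tolerance as a fraction of the segment SD.
#' @param dfaRange length-2 integer range of DFA box sizes (beats).
#' @param smoothWindowS smoothing window for instantaneous-HR curves, s.
#' @return a validated settings list.
#' @export
analysisSettings <- function(resampleRate = 4, detrend = c("linear", "none"),
                             welchWindowS = 64, welchOverlap = 0.5,
                             lfBand = c(0.04, 0.15), hfBand = c(0.15, 0.4),
                             entropyM = 2L, entropyRFactor = 0.2,
                             dfaRange = c(4L, 11L), smoothWindowS = 10) {
  detrend <- match.arg(detrend)
  .stopIfNot(.isScalar(resampleRate) && resampleRate > 0,
             "resampleRate must be positive")
  .stopIfNot(.isScalar(welchWindowS) && welchWindowS > 0,
             "welchWindowS must be positive")
  .stopIfNot(.isScalar(welchOverlap) && welchOverlap >= 0 && welchOverlap < 1,
             "welchOverlap must be in [0, 1)")
  .stopIfNot(length(lfBand) == 2 && length(hfBand) == 2 &&
               lfBand[1] < lfBand[2] && hfBand[1] < hfBand[2] &&
               lfBand[2] <= hfBand[1],
             "bands must be ordered and non-overlapping")
  .stopIfNot(entropyM >= 1, "entropyM must be >= 1")
  .stopIfNot(entropyRFactor > 0, "entropyRFactor must be positive")
  .stopIfNot(length(dfaRange) == 2 && dfaRange[1] >= 4 &&
               dfaRange[1] < dfaRange[2],
             "dfaRange must satisfy 4 <= min < max")
  .stopIfNot(.isScalar(smoothWindowS) && smoothWindowS >= 0,
             "smoothWindowS must be non-negative")
  list(resampleRate = resampleRate, detrend = detrend,
       welchWindowS = welchWindowS, welchOverlap = welchOverlap,
       lfBand = as.numeric(lfBand), hfBand = as.numeric(hfBand),
       entropyM = as.integer(entropyM), entropyRFactor = entropyRFactor,
       dfaRange = as.integer(dfaRange), smoothWindowS = smoothWindowS)
}

.rrValues <- function(rr) {
  if (is(rr, "RRSeries")) rr@intervals else as.numeric(rr)
}

#' Time-domain HRV indices
#'
#' Computes, on one RR segment: mean HR (`60000 / meanRR`, bpm), mean RR
#' (ms), SDNN (sample SD, n-1), CV (`100 * SDNN / meanRR`, %), RMSSD (ms),
#' and pNN50/pNN30 (% of successive differences strictly larger than
#' 50/30 ms).
#'
#' @param rr an [RRSeries-class] segment or a numeric vector of intervals
#'   (ms) with at least 2 intervals, all positive.
#' @return one-row data.frame with columns `mean_hr`, `mean_rr`, `sdnn`,
#'   `cv`, `rmssd`, `pnn50`, `pnn30`.
#' @examples
#' computeTimeIndices(c(800, 860, 870, 940))
#' @export
computeTimeIndices <- function(rr) {
  v <- .rrValues(rr)
  .stopIfNot(length(v) >= 2, "need at least 2 intervals")
  .stopIfNot(all(v > 0), "all intervals must be positive")
  d <- diff(v)
  meanRR <- mean(v)
  sdnn <- sd(v)
  data.frame(
    mean_hr = 60000 / meanRR,
    mean_rr = meanRR,
    sdnn = sdnn,
    cv = 100 * sdnn / meanRR,
    rmssd = sqrt(mean(d^2)),
    pnn50 = 100 * sum(abs(d) > 50) / length(d),
    pnn30 = 100 * sum(abs(d) > 30) / length(d))
}
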