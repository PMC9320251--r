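#' Detect R peaks in a single-lead ECG
#'
#' Pan-Tompkins-style detector: zero-phase band-pass 5-15 Hz
#' (2nd-order Butterworth, forward-backward), five-point derivative,
#' squaring, 150 ms moving-window integration, then an adaptive amplitude
#' threshold (running signal/noise peak estimates, threshold
#' `noise + 0.25 * (signal - noise)`) with a 200 ms refractory period.
#' Each accepted detection is refined to the local maximum of the raw
#' signal within +/- 40 ms, and the R amplitude is read off the raw signal
#' at the refined location.
#'
#' @param ecg an [ECGRecord-class] at least 2 s long.
#' @return a [BeatSeries-class]; empty (zero beats) for a flat-line record.
#' @export
detectRPeaks <- function(ecg) {
  .stopIfNot(is(ecg, "ECGRecord"), "ecg must be an ECGRecord")
  fs <- ecg@samplingRate
  x <- ecg@samples
  .stopIfNot(length(x) >= 2 * fs, "ECG record shorter than 2 s")
  if (sd(x) < .Machine$double.eps)
    return(BeatSeries(numeric(0), numeric(0), subjectId = ecg@subjectId))

  bf <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x)
  # five-point derivative, gain (fs/8) * [1 2 0 -2 -1]
  dcoef <- fs / 8 * c(1, 2, 0, -2, -1)
  xd <- as.numeric(stats::filter(xf, dcoef, sides = 2))
  xd[is.na(xd)] <- 0
  xs <- xd^2
  wl <- max(1L, round(0.150 * fs))
  mwi <- as.numeric(stats::filter(xs, rep(1 / wl, wl), sides = 2))
  mwi[is.na(mwi)] <- 0

  # candidate peaks: strict local maxima of the integrated signal
  n <- length(mwi)
  cand <- which(mwi[2:(n - 1)] > mwi[1:(n - 2)] &
                  mwi[2:(n - 1)] >= mwi[3:n]) + 1L
  if (!length(cand))
    return(BeatSeries(numeric(0), numeric(0), subjectId = ecg@subjectId))

  initN <- min(n, round(2 * fs))
  spki <- max(mwi[1:initN]) * 0.5
  npki <- mean(mwi[1:initN]) * 0.5
  refr <- 0.200 * fs
  accepted <- integer(0)
  lastBeat <- -Inf
  for (p in cand) {
    thr <- npki + 0.25 * (spki - npki)
    if (mwi[p] > thr) {
      if (p - lastBeat < refr) {
        # within refractory: keep the larger of the two detections
        if (length(accepted) && mwi[p] > mwi[accepted[length(accepted)]]) {
          accepted[length(accepted)] <- p
          lastBeat <- p
        }
        next
      }
      accepted <- c(accepted, p)
      lastBeat <- p
      spki <- 0.125 * mwi[p] + 0.875 * spki
    } else {
      npki <- 0.125 * mwi[p] + 0.875 * npki
    }
  }
  if (!length(accepted))
    return(BeatSeries(numeric(0), numeric(0), subjectId = ecg@subjectId))

  # refine to local raw-signal maximum within +/- 40 ms
  half <- as.integer(round(0.040 * fs))
  refined <- vapply(accepted, function(p) {
    i1 <- max(1L, p - half); i2 <- min(n, p + half)
    as.integer(i1 + which.max(x[i1:i2]) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  BeatSeries(rTimes = (refined - 1L) / fs, rAmplitudes = x[refined],
             subjectId = ecg@subjectId)
}

#' Derive an RR-interval series from detected beats
#'
#' Intervals are successive beat-time differences in milliseconds; every
#' interval starts out annotated `"normal"`.
#'
#' @param beats a [BeatSeries-class] with at least two beats.
#' @return an [RRSeries-class]; `beatTimes` are the interval end times.
#' @export
extractRR <- function(beats) {
  .stopIfNot(is(beats, "BeatSeries"), "beats must be a BeatSeries")
  .stopIfNot(length(beats) >= 2, "need at least 2 beats to form intervals")
  RRSeries(intervals = diff(beats@rTimes) * 1000,
           beatTimes = beats@rTimes[-1],
           subjectId = beats@subjectId)
}
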