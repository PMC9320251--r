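#' Resample an RR series to a uniform tachogram
#'
#' Cubic-spline interpolation of the interval value against its end time,
#' evaluated on a uniform grid at `settings$resampleRate` (default 4 Hz)
#' spanning the segment (both endpoints included). With
#' `settings$detrend == "linear"` the least-squares line is removed from
#' the resampled series.
#'
#' @param rr an [RRSeries-class] segment (>= 4 intervals).
#' @param settings an [analysisSettings()] list.
#' @return a list with `time` (s), `values` (ms, possibly detrended) and
#'   `rate` (Hz).
#' @export
resampleRR <- function(rr, settings = analysisSettings()) {
  .stopIfNot(is(rr, "RRSeries"), "rr must be an RRSeries")
  .stopIfNot(length(rr) >= 4, "need at least 4 intervals to resample")
  t <- rr@beatTimes
  .stopIfNot(!anyDuplicated(t), "duplicate beat times")
  span <- t[length(t)] - t[1]
  if (span < 2 * settings$welchWindowS)
    warning(sprintf(
      "segment spans %.0f s; at least %.0f s recommended for spectral analysis",
      span, 2 * settings$welchWindowS))
  grid <- seq(t[1], t[length(t)], by = 1 / settings$resampleRate)
  sf <- splinefun(t, rr@intervals, method = "natural")
  v <- sf(grid)
  if (settings$detrend == "linear") v <- .detrendLinear(v)
  list(time = grid, values = v, rate = settings$resampleRate)
}

#' Welch power spectral density of a tachogram
#'
#' Hann-windowed segments of `welchWindowS` seconds with `welchOverlap`
#' overlap; per-segment mean removal; averaged one-sided periodograms.
#' `total_power_ms2` is the trapezoidal integral of the density.
#'
#' @param tachogram output of [resampleRR()], or any list with `values`
#'   and `rate`.
#' @param settings an [analysisSettings()] list.
#' @return a list with `frequencies` (Hz), `power` (ms^2/Hz),
#'   `total_power_ms2` and `n_segments`.
#' @export
computePsdWelch <- function(tachogram, settings = analysisSettings()) {
  .stopIfNot(is.list(tachogram) && !is.null(tachogram$values) &&
               !is.null(tachogram$rate),
             "tachogram must be the output of resampleRR()")
  x <- tachogram$values
  fs <- tachogram$rate
  minN <- round(settings$welchWindowS * fs)
  .stopIfNot(length(x) >= minN,
             sprintf("tachogram too short for Welch PSD: need >= %d samples (%g s at %g Hz), got %d",
                     minN, settings$welchWindowS, fs, length(x)))
  est <- .welchPsd(x, fs, settings$welchWindowS, settings$welchOverlap)
  list(frequencies = est$frequencies, power = est$power,
       total_power_ms2 = pracma::trapz(est$frequencies, est$power),
       n_segments = est$nSegments)
}

#' Frequency-domain HRV indices from a spectrum
#'
#' Trapezoidal band integrals of the PSD over the LF (0.04-0.15 Hz) and HF
#' (0.15-0.4 Hz) bands; normalized units are each band as a percentage of
#' LF + HF, so `lf_nu + hf_nu = 100` whenever both are defined. The EDR
#' column is returned as `NA`; it comes from [estimateEdr()].
#'
#' @param spectrum output of [computePsdWelch()].
#' @param settings an [analysisSettings()] list.
#' @return one-row data.frame with `lf_ms2`, `hf_ms2`, `lf_nu`, `hf_nu`,
#'   `lf_hf`, `edr`.
#' @export
computeFreqIndices <- function(spectrum, settings = analysisSettings()) {
  .stopIfNot(is.list(spectrum) && !is.null(spectrum$frequencies),
             "spectrum must be the output of computePsdWelch()")
  f <- spectrum$frequencies
  p <- spectrum$power
  lf <- .bandPower(f, p, settings$lfBand[1], settings$lfBand[2])
  hf <- .bandPower(f, p, settings$hfBand[1], settings$hfBand[2])
  if (lf + hf <= 0) {
    warning("LF + HF power is zero; normalized units undefined")
    lfnu <- hfnu <- NA_real_
  } else {
    lfnu <- 100 * lf / (lf + hf)
    hfnu <- 100 * hf / (lf + hf)
  }
  if (hf <= 0) {
    if (lf + hf > 0) warning("HF power is zero; LF/HF undefined")
    ratio <- NA_real_
  } else {
    ratio <- lf / hf
  }
  data.frame(lf_ms2 = lf, hf_ms2 = hf, lf_nu = lfnu, hf_nu = hfnu,
             lf_hf = ratio, edr = NA_real_)
}

#' ECG-derived respiration frequency
#'
#' Primary path (when a [BeatSeries-class] with amplitudes is given): the
#' R-amplitude sequence is spline-resampled at 4 Hz, linearly detrended,
#' and the respiration frequency is the location of the Welch PSD maximum
#' in 0.1-0.5 Hz. Fallback path (RR series): the location of the HF-band
#' PSD maximum of the tachogram, since respiratory sinus arrhythmia
#' imprints the breathing frequency on the HF band.
#'
#' @param x a [BeatSeries-class] with amplitudes or an [RRSeries-class].
#' @param settings an [analysisSettings()] list.
#' @return list with `edr` (Hz or NA) and `path`
#'   (`"r_amplitude"` or `"rr_hf"`).
#' @export
estimateEdr <- function(x, settings = analysisSettings()) {
  if (is(x, "BeatSeries")) {
    if (length(x) < 60) {
      warning("fewer than 60 beats; EDR estimate refused")
      return(list(edr = NA_real_, path = "r_amplitude"))
    }
    t <- x@rTimes
    a <- x@rAmplitudes
    if (anyNA(a) || sd(a) < 1e-10) {
      warning("R amplitudes missing or constant; EDR undefined")
      return(list(edr = NA_real_, path = "r_amplitude"))
    }
    grid <- seq(t[1], t[length(t)], by = 1 / 4)
    v <- .detrendLinear(splinefun(t, a, method = "natural")(grid))
    win <- min(settings$welchWindowS, floor(length(grid) / 4 / 2) * 2)
    if (win < 16) {
      warning("record too short for EDR spectral estimate")
      return(list(edr = NA_real_, path = "r_amplitude"))
    }
    est <- .welchPsd(v, 4, win, settings$welchOverlap)
    sel <- est$frequencies >= 0.1 & est$frequencies <= 0.5
    if (!any(sel) || max(est$power[sel]) <= 1e-12 * max(1, max(est$power))) {
      warning("flat amplitude spectrum; EDR undefined")
      return(list(edr = NA_real_, path = "r_amplitude"))
    }
    f <- est$frequencies[sel][which.max(est$power[sel])]
    return(list(edr = f, path = "r_amplitude"))
  }
  if (is(x, "RRSeries")) {
    if (length(x) < 60) {
      warning("fewer than 60 beats; EDR estimate refused")
      return(list(edr = NA_real_, path = "rr_hf"))
    }
    tach <- resampleRR(x, settings)
    spec <- computePsdWelch(tach, settings)
    sel <- spec$frequencies >= settings$hfBand[1] &
      spec$frequencies <= settings$hfBand[2]
    if (!any(sel) || max(spec$power[sel]) <= 0) {
      warning("no HF power; EDR undefined")
      return(list(edr = NA_real_, path = "rr_hf"))
    }
    f <- spec$frequencies[sel][which.max(spec$power[sel])]
    return(list(edr = f, path = "rr_hf"))
  }
  stop("x must be a BeatSeries or RRSeries", call. = FALSE)
}
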