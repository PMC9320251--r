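#' IPFM modulation configuration
#'
#' Parameters of the integral pulse frequency modulation (IPFM) model used
#' to generate RR-interval series with prescribed spectral content. The
#' instantaneous beat rate is `(1 + m(t)) / meanRR` with
#' `m(t) = ampLF * sin(2*pi*freqLF*t) + ampHF * sin(2*pi*freqHF*t) + noise`,
#' and a beat is emitted each time the integrated rate crosses an integer.
#' The broadband noise term is built from Gaussian increments low-pass
#' filtered at 0.5 Hz so modulation stays below the upper HF band edge.
#'
#' @param meanRR mean cardiac period in ms.
#' @param ampLF,freqLF amplitude (dimensionless) and frequency (Hz) of the
#'   low-frequency modulation; the LF band of interest is 0.04-0.15 Hz.
#' @param ampHF,freqHF amplitude and frequency of the high-frequency
#'   (respiratory) modulation; the HF band of interest is 0.15-0.4 Hz.
#' @param noiseSd standard deviation of the band-limited noise modulation.
#' @param durationS record duration in seconds.
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @return a validated configuration list.
#' @export
ipfmConfig <- function(meanRR = 800, ampLF = 0.06, freqLF = 0.095,
                       ampHF = 0.03, freqHF = 0.275, noiseSd = 0.01,
                       durationS = 300, seed = 1L) {
  cfg <- list(meanRR = meanRR, ampLF = ampLF, freqLF = freqLF,
              ampHF = ampHF, freqHF = freqHF, noiseSd = noiseSd,
              durationS = durationS, seed = as.integer(seed))
  num <- unlist(cfg[c("meanRR", "ampLF", "freqLF", "ampHF", "freqHF",
                      "noiseSd", "durationS")])
  .stopIfNot(all(vapply(num, .isScalar, logical(1))),
             "all IPFM parameters must be single finite numbers")
  .stopIfNot(meanRR > 0, "meanRR must be positive")
  .stopIfNot(durationS > 0, "durationS must be positive")
  .stopIfNot(ampLF >= 0 && ampHF >= 0 && noiseSd >= 0,
             "modulation amplitudes must be non-negative")
  .stopIfNot(ampLF + ampHF + 3 * noiseSd < 1,
             "total modulation depth (ampLF + ampHF + 3*noiseSd) must be < 1 ",
             "so the instantaneous rate stays positive")
  if (ampLF > 0 && (freqLF < 0.04 || freqLF > 0.15))
    warning("freqLF lies outside the 0.04-0.15 Hz LF band")
  if (ampHF > 0 && (freqHF <= 0.15 || freqHF > 0.4))
    warning("freqHF lies outside the 0.15-0.4 Hz HF band")
  cfg
}

#' Walking-test heart-rate profile configuration
#'
#' Deterministic target-HR trajectory for the three protocol phases:
#' a flat baseline plateau, an exponential rise toward `hrMax` during the
#' walk (optionally with a slow linear pacing decline after the initial
#' rise), and an exponential decay during recovery toward
#' `hrBaseline + recoveryOffset`. A positive `recoveryOffset` emulates the
#' frail phenotype, whose mean HR does not return to its baseline value
#' within the 5-min recovery.
#'
#' @param hrBaseline baseline heart rate in bpm.
#' @param hrMax target maximal heart rate during the walk (bpm).
#' @param riseTau exponential rise time constant after walk onset (s).
#' @param paceDrift linear decline of the walking target HR (bpm/s),
#'   representing pacing adaptation after the initial effort; default 0.
#' @param walkDurationS duration of the walk (s).
#' @param recoveryTau exponential recovery time constant (s).
#' @param recoveryOffset residual HR elevation at the end of recovery (bpm,
#'   must be non-negative).
#' @param baselineS,recoveryS durations of the rest phases (s), default 300.
#' @return a validated configuration list.
#' @export
walkProfileConfig <- function(hrBaseline = 75, hrMax = 100, riseTau = 15,
                              paceDrift = 0, walkDurationS = 180,
                              recoveryTau = 30, recoveryOffset = 0,
                              baselineS = 300, recoveryS = 300) {
  cfg <- list(hrBaseline = hrBaseline, hrMax = hrMax, riseTau = riseTau,
              paceDrift = paceDrift, walkDurationS = walkDurationS,
              recoveryTau = recoveryTau, recoveryOffset = recoveryOffset,
              baselineS = baselineS, recoveryS = recoveryS)
  .stopIfNot(all(vapply(cfg, .isScalar, logical(1))),
             "all walk profile parameters must be single finite numbers")
  .stopIfNot(hrBaseline > 0, "hrBaseline must be positive")
  .stopIfNot(hrMax >= hrBaseline, "hrMax must be >= hrBaseline")
  .stopIfNot(riseTau > 0 && recoveryTau > 0, "time constants must be positive")
  .stopIfNot(walkDurationS > 0 && baselineS > 0 && recoveryS > 0,
             "all phase durations must be positive")
  .stopIfNot(recoveryOffset >= 0, "recoveryOffset must be non-negative")
  .stopIfNot(paceDrift >= 0, "paceDrift must be non-negative")
  if (walkDurationS < riseTau / 10)
    warning("walkDurationS < riseTau/10: the target HRMax is unreachable ",
            "within the walk")
  cfg
}

#' Synthetic ECG configuration
#'
#' Parameters of the QRS-template ECG synthesizer. Each beat contributes a
#' Mexican-hat (Ricker) pulse of the configured width; R amplitudes are
#' sinusoidally modulated at the respiratory frequency, which is what the
#' ECG-derived respiration (EDR) estimator recovers.
#'
#' @param samplingRate sampling frequency in Hz (>= 100; the study device
#'   digitized at 250 Hz).
#' @param qrsWidthMs full width of the QRS template in ms.
#' @param qrsAmplitudeMv R-wave amplitude in mV.
#' @param amplitudeModulationFreq respiratory modulation frequency of the
#'   R amplitude (Hz).
#' @param amplitudeModulationDepth relative modulation depth (fraction of
#'   `qrsAmplitudeMv`).
#' @param noiseSd additive Gaussian noise SD in mV.
#' @param seed integer RNG seed.
#' @return a validated configuration list.
#' @export
ecgSynthConfig <- function(samplingRate = 250, qrsWidthMs = 80,
                           qrsAmplitudeMv = 1, amplitudeModulationFreq = 0.25,
                           amplitudeModulationDepth = 0.1, noiseSd = 0,
                           seed = 1L) {
  cfg <- list(samplingRate = samplingRate, qrsWidthMs = qrsWidthMs,
              qrsAmplitudeMv = qrsAmplitudeMv,
              amplitudeModulationFreq = amplitudeModulationFreq,
              amplitudeModulationDepth = amplitudeModulationDepth,
              noiseSd = noiseSd, seed = as.integer(seed))
  .stopIfNot(all(vapply(cfg[-7], .isScalar, logical(1))),
             "all ECG parameters must be single finite numbers")
  .stopIfNot(samplingRate >= 100, "samplingRate must be >= 100 Hz")
  .stopIfNot(qrsWidthMs > 0 && qrsAmplitudeMv > 0,
             "QRS width and amplitude must be positive")
  .stopIfNot(amplitudeModulationFreq >= 0 && amplitudeModulationDepth >= 0 &&
               amplitudeModulationDepth < 1 && noiseSd >= 0,
             "invalid modulation or noise parameters")
  cfg
}

# Band-limited Gaussian modulation noise on the solver grid.
.ipfmNoise <- function(n, fsGrid, noiseSd) {
  if (noiseSd <= 0 || n < 16L) return(numeric(n))
  z <- rnorm(n)
  bf <- signal::butter(2, 0.5 / (fsGrid / 2), type = "low")
  z <- signal::filtfilt(bf, z)
  s <- sd(z)
  if (s < .Machine$double.eps) return(numeric(n))
  z / s * noiseSd
}

# Shared IPFM beat solver: rateFun(t) gives instantaneous rate in beats/s
# (already including modulation). Returns beat times starting at 0.
.ipfmSolve <- function(tGrid, rate) {
  rate <- pmax(rate, 1e-3)
  dt <- tGrid[2] - tGrid[1]
  M <- c(0, cumsum((rate[-1] + rate[-length(rate)]) / 2 * dt))
  nBeats <- floor(M[length(M)])
  if (nBeats < 1) stop("record too short: no complete beat", call. = FALSE)
  k <- seq_len(nBeats)
  i <- findInterval(k, M)
  i[i >= length(M)] <- length(M) - 1L
  tk <- tGrid[i] + (k - M[i]) / (M[i + 1L] - M[i]) * dt
  c(0, tk)
}

#' Generate an RR-interval series with the IPFM model
#'
#' Emits a beat each time the integral of the modulated instantaneous rate
#' crosses an integer. The integral is accumulated by trapezoidal rule on a
#' 100 Hz grid and each crossing is refined by linear interpolation, giving
#' sub-millisecond beat placement. With all modulation amplitudes zero the
#' output intervals equal `meanRR` exactly.
#'
#' @param config an [ipfmConfig()] list.
#' @return an [RRSeries-class]; `beatTimes` are interval end times and the
#'   first beat sits at t = 0.
#' @examples
#' rr <- generateIpfmRR(ipfmConfig(ampLF = 0, ampHF = 0, noiseSd = 0,
#'                                 durationS = 8, seed = 1))
#' rrIntervals(rr)  # all exactly 800 ms
#' @export
generateIpfmRR <- function(config) {
  .stopIfNot(is.list(config) && !is.null(config$meanRR),
             "config must come from ipfmConfig()")
  fsGrid <- 100
  tGrid <- seq(0, config$durationS, by = 1 / fsGrid)
  set.seed(config$seed)
  m <- config$ampLF * sin(2 * pi * config$freqLF * tGrid) +
    config$ampHF * sin(2 * pi * config$freqHF * tGrid) +
    .ipfmNoise(length(tGrid), fsGrid, config$noiseSd)
  beats <- .ipfmSolve(tGrid, (1 + m) / (config$meanRR / 1000))
  RRSeries(intervals = diff(beats) * 1000, beatTimes = beats[-1])
}

# Deterministic target HR (bpm) of the walking-test profile at times t (s).
.walkTargetHr <- function(t, walk) {
  B <- walk$baselineS
  W <- walk$walkDurationS
  hr <- rep(walk$hrBaseline, length(t))
  inWalk <- t >= B & t < B + W
  tw <- t[inWalk] - B
  hr[inWalk] <- pmax(
    30,
    walk$hrBaseline + (walk$hrMax - walk$hrBaseline) *
      (1 - exp(-tw / walk$riseTau)) - walk$paceDrift * tw)
  inRec <- t >= B + W
  hrWalkEnd <- pmax(
    30,
    walk$hrBaseline + (walk$hrMax - walk$hrBaseline) *
      (1 - exp(-W / walk$riseTau)) - walk$paceDrift * W)
  target <- walk$hrBaseline + walk$recoveryOffset
  tr <- t[inRec] - (B + W)
  hr[inRec] <- target + (hrWalkEnd - target) * exp(-tr / walk$recoveryTau)
  hr
}

#' Generate a walking-test RR series
#'
#' Superposes IPFM modulation (LF/HF sinusoids plus band-limited noise from
#' `modulation`) on the phase-structured target-HR trajectory defined by
#' `walk`: baseline plateau, exponential rise toward `hrMax` while walking,
#' and exponential recovery toward `hrBaseline + recoveryOffset`. The
#' returned series carries its [PhaseSegmentation-class] and per-interval
#' phase labels (an interval belongs to the phase containing its end time;
#' intervals ending exactly on a boundary go to the later phase).
#'
#' @param walk a [walkProfileConfig()] list.
#' @param modulation an [ipfmConfig()] list; its `meanRR` and `durationS`
#'   are ignored (the rate comes from the walk profile).
#' @return an [RRSeries-class] with phases and segmentation attached.
#' @export
generateWalkTestRR <- function(walk, modulation = ipfmConfig()) {
  .stopIfNot(is.list(walk) && !is.null(walk$hrBaseline),
             "walk must come from walkProfileConfig()")
  .stopIfNot(is.list(modulation) && !is.null(modulation$ampLF),
             "modulation must come from ipfmConfig()")
  fsGrid <- 100
  total <- walk$baselineS + walk$walkDurationS + walk$recoveryS
  tGrid <- seq(0, total, by = 1 / fsGrid)
  set.seed(modulation$seed)
  m <- modulation$ampLF * sin(2 * pi * modulation$freqLF * tGrid) +
    modulation$ampHF * sin(2 * pi * modulation$freqHF * tGrid) +
    .ipfmNoise(length(tGrid), fsGrid, modulation$noiseSd)
  rate <- .walkTargetHr(tGrid, walk) / 60 * (1 + m)
  beats <- .ipfmSolve(tGrid, rate)
  seg <- PhaseSegmentation(
    tBaselineStart = 0, tWalkStart = walk$baselineS,
    tWalkEnd = walk$baselineS + walk$walkDurationS,
    tRecoveryEnd = total)
  ends <- beats[-1]
  RRSeries(intervals = diff(beats) * 1000, beatTimes = ends,
           phases = .assignPhases(ends, seg), segmentation = seg)
}

# Phase of each interval end time under the "later phase at boundaries" rule.
.assignPhases <- function(endTimes, seg) {
  ph <- rep(NA_character_, length(endTimes))
  inRecord <- endTimes > seg@tBaselineStart & endTimes <= seg@tRecoveryEnd
  ph[inRecord & endTimes < seg@tWalkStart] <- "baseline"
  ph[inRecord & endTimes >= seg@tWalkStart & endTimes < seg@tWalkEnd] <- "walking"
  ph[inRecord & endTimes >= seg@tWalkEnd] <- "recovery"
  ph
}

#' Synthesize a single-lead ECG from a beat sequence
#'
#' Places one Mexican-hat (Ricker) QRS template at each beat time on the
#' configured sampling grid; R amplitudes are modulated sinusoidally at the
#' respiratory frequency and Gaussian noise is added. The ground-truth beat
#' times are stored in the returned record for detector scoring.
#'
#' @param beats an [RRSeries-class] or [BeatSeries-class].
#' @param config an [ecgSynthConfig()] list.
#' @return an [ECGRecord-class] with `truthBeatTimes` filled in.
#' @export
generateEcgFromBeats <- function(beats, config = ecgSynthConfig()) {
  if (is(beats, "RRSeries")) {
    .stopIfNot(length(beats) >= 1, "beats must contain at least one interval")
    t0 <- beats@beatTimes[1] - beats@intervals[1] / 1000
    beatT <- c(t0, beats@beatTimes)
    minRR <- min(beats@intervals)
  } else if (is(beats, "BeatSeries")) {
    .stopIfNot(length(beats) >= 1, "beats must be non-empty")
    beatT <- beats@rTimes
    minRR <- if (length(beatT) > 1) min(diff(beatT)) * 1000 else Inf
  } else {
    stop("beats must be an RRSeries or BeatSeries", call. = FALSE)
  }
  .stopIfNot(config$qrsWidthMs < minRR,
             "qrsWidthMs must be smaller than the minimum RR interval ",
             "(overlapping QRS templates)")
  fs <- config$samplingRate
  # half-second lead-in/out so edge templates are never truncated
  beatT <- beatT - min(beatT) + 0.5
  n <- ceiling((max(beatT) + 0.5) * fs) + 1L
  x <- numeric(n)
  sigma <- config$qrsWidthMs / 1000 / 6   # template support ~ +/- 3 sigma
  halfWin <- config$qrsWidthMs / 1000     # evaluate out to 6 sigma (~0 there)
  amps <- config$qrsAmplitudeMv *
    (1 + config$amplitudeModulationDepth *
       sin(2 * pi * config$amplitudeModulationFreq * beatT))
  for (b in seq_along(beatT)) {
    i1 <- max(1L, floor((beatT[b] - halfWin) * fs) + 1L)
    i2 <- min(n, ceiling((beatT[b] + halfWin) * fs) + 1L)
    tau <- ((i1:i2) - 1L) / fs - beatT[b]
    x[i1:i2] <- x[i1:i2] +
      amps[b] * (1 - (tau / sigma)^2) * exp(-tau^2 / (2 * sigma^2))
  }
  if (config$noiseSd > 0) {
    set.seed(config$seed)
    x <- x + rnorm(n, sd = config$noiseSd)
  }
  ECGRecord(samples = x, samplingRate = fs, truthBeatTimes = beatT)
}

# Per-group generative parameter distributions (mean, sd). Chosen once to
# reproduce the direction of the observed group differences: frail subjects
# get a lower LF:HF amplitude ratio, slower rise and recovery time
# constants, a slower gait and a positive residual HR elevation after
# recovery; young subjects the opposite.
.groupProfiles <- list(
  C1 = list(hrBaseline = c(81, 6),  hrMax = c(107, 5), riseTau = c(12, 2),
            paceDrift = 0.05, recoveryTau = c(25, 5),
            recoveryOffset = c(0, 0),   gaitSpeed = c(1.30, 0.12),
            ampLF = c(0.085, 0.012), ampHF = c(0.042, 0.008),
            freqLF = c(0.095, 0.008), freqHF = c(0.25, 0.02),
            noiseSd = 0.015),
  C2 = list(hrBaseline = c(74, 6),  hrMax = c(104, 6), riseTau = c(13, 2),
            paceDrift = 0.05, recoveryTau = c(30, 6),
            recoveryOffset = c(0.5, 0.5), gaitSpeed = c(1.25, 0.12),
            ampLF = c(0.070, 0.012), ampHF = c(0.040, 0.008),
            freqLF = c(0.095, 0.008), freqHF = c(0.24, 0.02),
            noiseSd = 0.015),
  nF = list(hrBaseline = c(76, 5),  hrMax = c(98, 4),  riseTau = c(18, 3),
            paceDrift = 0.05, recoveryTau = c(40, 8),
            recoveryOffset = c(0.5, 0.5), gaitSpeed = c(1.00, 0.10),
            ampLF = c(0.050, 0.008), ampHF = c(0.023, 0.005),
            freqLF = c(0.095, 0.008), freqHF = c(0.22, 0.02),
            noiseSd = 0.010),
  F  = list(hrBaseline = c(74, 6),  hrMax = c(90, 4),  riseTau = c(55, 10),
            paceDrift = 0.02, recoveryTau = c(90, 15),
            recoveryOffset = c(4, 1.5),  gaitSpeed = c(0.70, 0.10),
            ampLF = c(0.035, 0.006), ampHF = c(0.029, 0.005),
            freqLF = c(0.095, 0.008), freqHF = c(0.29, 0.02),
            noiseSd = 0.010)
)

#' Synthetic cohort configuration
#'
#' Group sizes and random seed for [generateCohort()]. Group labels follow
#' the study design: `C1` young adults, `C2` middle-aged adults, `nF`
#' non-frail older adults, `F` frail older adults. Default sizes are the
#' study's (21/16/15/28). Per-group generative parameter distributions are
#' fixed package defaults (see the methods vignette); individual entries can
#' be overridden through `profiles`.
#'
#' @param n named integer vector of group sizes; names drawn from
#'   `c("C1", "C2", "nF", "F")`.
#' @param seed integer RNG seed (mandatory).
#' @param ecg logical, also synthesize an ECG per subject (default FALSE).
#' @param profiles optional named list overriding entries of the per-group
#'   parameter distributions.
#' @return a validated configuration list.
#' @export
cohortConfig <- function(n = c(C1 = 21, C2 = 16, nF = 15, F = 28),
                         seed = 1L, ecg = FALSE, profiles = NULL) {
  .stopIfNot(length(n) >= 1 && !is.null(names(n)) &&
               all(names(n) %in% names(.groupProfiles)),
             "n must be a named vector with names among C1, C2, nF, F")
  n <- n[n > 0]
  .stopIfNot(length(n) >= 1 && sum(n) >= 1,
             "at least one group must have at least one subject")
  prof <- .groupProfiles[names(n)]
  if (!is.null(profiles)) {
    for (g in names(profiles)) {
      .stopIfNot(g %in% names(prof), "unknown group in profiles: ", g)
      prof[[g]][names(profiles[[g]])] <- profiles[[g]]
    }
  }
  list(n = n, seed = as.integer(seed), ecg = isTRUE(ecg), profiles = prof)
}

.drawParam <- function(spec, lo = -Inf, hi = Inf) {
  if (length(spec) == 1L) return(min(max(spec, lo), hi))
  min(max(rnorm(1, spec[1], spec[2]), lo), hi)
}

#' Generate a synthetic walking-test cohort
#'
#' Draws per-subject walk-profile and IPFM parameters from the group
#' distributions, generates one walking-test RR record per subject (and
#' optionally an ECG), and assembles a manifest. Each subject's walk
#' duration is `160 m / gait speed`. Fixed seed gives an identical cohort.
#'
#' @param config a [cohortConfig()] list.
#' @param dir optional directory; when given, RR (and ECG) files plus
#'   `manifest.csv` are written there in the package's plain-text formats.
#' @return a list with `subjects` (named list; each element has `rr`,
#'   optionally `ecg`, `group`, `id`) and `manifest` (data.frame with
#'   subject_id, group, rr_path, ecg_path, t_walk_start_s, t_walk_end_s).
#' @export
generateCohort <- function(config, dir = NULL) {
  .stopIfNot(is.list(config) && !is.null(config$n),
             "config must come from cohortConfig()")
  distM <- walkTestProtocol()$distanceM
  nTotal <- sum(config$n)
  seeds <- .childSeeds(config$seed, nTotal + 1L)
  subjects <- list()
  rows <- list()
  k <- 0L
  set.seed(seeds[nTotal + 1L])
  paramDraws <- list()
  for (g in names(config$n)) {           # draw all parameters first so the
    p <- config$profiles[[g]]            # stream is independent of ecg flag
    for (i in seq_len(config$n[[g]])) {
      k <- k + 1L
      paramDraws[[k]] <- list(
        g = g, i = i,
        hrBaseline = .drawParam(p$hrBaseline, lo = 45),
        hrMax = .drawParam(p$hrMax, lo = 60),
        riseTau = .drawParam(p$riseTau, lo = 4),
        recoveryTau = .drawParam(p$recoveryTau, lo = 8),
        recoveryOffset = .drawParam(p$recoveryOffset, lo = 0),
        gaitSpeed = .drawParam(p$gaitSpeed, lo = 0.4),
        ampLF = .drawParam(p$ampLF, lo = 0.005),
        ampHF = .drawParam(p$ampHF, lo = 0.005),
        freqLF = .drawParam(p$freqLF, lo = 0.05, hi = 0.14),
        freqHF = .drawParam(p$freqHF, lo = 0.16, hi = 0.39),
        paceDrift = p$paceDrift[1], noiseSd = p$noiseSd[1])
    }
  }
  for (k in seq_len(nTotal)) {
    d <- paramDraws[[k]]
    id <- sprintf("%s_%02d", d$g, d$i)
    walk <- walkProfileConfig(
      hrBaseline = d$hrBaseline, hrMax = max(d$hrMax, d$hrBaseline),
      riseTau = d$riseTau, paceDrift = d$paceDrift,
      walkDurationS = distM / d$gaitSpeed,
      recoveryTau = d$recoveryTau, recoveryOffset = d$recoveryOffset)
    modo <- ipfmConfig(ampLF = d$ampLF, freqLF = d$freqLF, ampHF = d$ampHF,
                       freqHF = d$freqHF, noiseSd = d$noiseSd,
                       seed = seeds[k])
    rr <- generateWalkTestRR(walk, modo)
    rr@subjectId <- id
    subj <- list(rr = rr, group = d$g, id = id)
    if (config$ecg) {
      subj$ecg <- generateEcgFromBeats(
        rr, ecgSynthConfig(noiseSd = 0.02, seed = seeds[k]))
      subj$ecg@subjectId <- id
    }
    subjects[[id]] <- subj
    seg <- rr@segmentation
    rows[[k]] <- data.frame(
      subject_id = id, group = d$g,
      rr_path = if (is.null(dir)) NA_character_ else
        file.path(dir, paste0(id, "_rr.txt")),
      ecg_path = if (config$ecg && !is.null(dir))
        file.path(dir, paste0(id, "_ecg.csv")) else NA_character_,
      t_walk_start_s = seg@tWalkStart, t_walk_end_s = seg@tWalkEnd,
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (s in subjects) {
      writeRR(s$rr, file.path(dir, paste0(s$id, "_rr.txt")))
      if (!is.null(s$ecg))
        writeEcg(s$ecg, file.path(dir, paste0(s$id, "_ecg.csv")))
    }
    writeManifest(manifest, file.path(dir, "manifest.csv"))
  }
  list(subjects = subjects, manifest = manifest)
}
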