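# Independent brute-force oracles and fixture builders used across tests.

# Sample entropy straight from its definition: unordered pairs of distinct
# templates (both lengths over the first N-m starting points), Chebyshev
# distance, matches <= r. Returns Inf when no (m+1)-matches exist.
oracleSampEn <- function(x, m = 2L, rFactor = 0.2) {
  r <- rFactor * sd(x)
  N <- length(x)
  nT <- N - m
  B <- 0L; A <- 0L
  for (i in 1:(nT - 1)) {
    for (j in (i + 1):nT) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) B <- B + 1L
      if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r) A <- A + 1L
    }
  }
  if (B == 0L || A == 0L) return(Inf)
  -log(A / B)
}

# Approximate entropy with self-matches, straight from the definition.
oracleApEn <- function(x, m = 2L, rFactor = 0.2) {
  r <- rFactor * sd(x)
  N <- length(x)
  phi <- function(mm) {
    nT <- N - mm + 1L
    cs <- numeric(nT)
    for (i in 1:nT) {
      cnt <- 0L
      for (j in 1:nT)
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r)
          cnt <- cnt + 1L
      cs[i] <- cnt / nT
    }
    mean(log(cs))
  }
  phi(m) - phi(m + 1L)
}

# Exhaustive orthogonal-distance scan over every candidate threshold
# (including sentinels); returns the minimal achievable distance to (0, 1).
oracleMinRocDistance <- function(values, labels, positive, orientation) {
  pos <- labels == positive
  thr <- c(-Inf, sort(unique(values)), Inf)
  dmin <- Inf
  for (c0 in thr) {
    pred <- if (orientation == "positive_if_greater") values >= c0 else
      values <= c0
    tpr <- sum(pred & pos) / sum(pos)
    fpr <- sum(pred & !pos) / sum(!pos)
    dmin <- min(dmin, sqrt(fpr^2 + (1 - tpr)^2))
  }
  dmin
}

# Two-sided Fisher p-value for a 2x2 table by direct hypergeometric
# summation: sum the probabilities of all tables with the same margins
# whose probability does not exceed the observed one.
oracleFisher2x2 <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  p <- dhyper(support, m, n, k)
  pObs <- dhyper(x, m, n, k)
  sum(p[p <= pObs * (1 + 1e-7)])
}

# A quiet 5-min stationary RR segment with both LF and HF content.
makeRestSegment <- function(seed = 1, durationS = 300, ampLF = 0.06,
                            ampHF = 0.03, noiseSd = 0.01, meanRR = 800) {
  suppressWarnings(generateIpfmRR(ipfmConfig(
    meanRR = meanRR, ampLF = ampLF, ampHF = ampHF, noiseSd = noiseSd,
    durationS = durationS, seed = seed)))
}

# A full walking-test record with moderate modulation.
makeWalkRecord <- function(seed = 1, hrBaseline = 75, hrMax = 100,
                           riseTau = 15, paceDrift = 0.05,
                           walkDurationS = 180, recoveryTau = 30,
                           recoveryOffset = 0, noiseSd = 0.01) {
  generateWalkTestRR(
    walkProfileConfig(hrBaseline = hrBaseline, hrMax = hrMax,
                      riseTau = riseTau, paceDrift = paceDrift,
                      walkDurationS = walkDurationS,
                      recoveryTau = recoveryTau,
                      recoveryOffset = recoveryOffset),
    ipfmConfig(ampLF = 0.05, ampHF = 0.025, noiseSd = noiseSd,
               seed = seed))
}

# An RRSeries with given interval values and all-normal annotations.
plainRR <- function(intervals) RRSeries(intervals = intervals)
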