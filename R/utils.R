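#' @importFrom stats fft approx splinefun lm lm.fit coef var sd median
#' @importFrom stats quantile setNames rnorm runif pnorm qnorm
NULL

.stopIfNot <- function(cond, ...) if (!isTRUE(cond)) stop(..., call. = FALSE)

.isScalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Hann-windowed Welch power spectral density (one-sided).
# x: uniformly sampled series; fs in Hz; windowS segment length in seconds;
# overlap in [0, 1). Each segment is mean-removed before windowing. The
# density is scaled so that sum(power) * df equals the series variance
# (Parseval, up to window edge effects).
.welchPsd <- function(x, fs, windowS, overlap = 0.5) {
  L <- round(windowS * fs)
  .stopIfNot(L >= 8, "Welch window too short")
  .stopIfNot(length(x) >= L,
             sprintf("series too short for Welch estimate: need >= %d samples, got %d",
                     L, length(x)))
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  n <- seq_len(L) - 1L
  w <- 0.5 - 0.5 * cos(2 * pi * n / (L - 1))        # Hann
  U <- sum(w^2)
  nf <- floor(L / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- seg - mean(seg)
    X <- fft(seg * w)
    P <- (Mod(X[seq_len(nf)])^2) / (fs * U)
    # one-sided: double everything except DC (and Nyquist when L is even)
    if (L %% 2 == 0) {
      if (nf > 2L) P[2:(nf - 1L)] <- 2 * P[2:(nf - 1L)]
    } else if (nf > 1L) {
      P[2:nf] <- 2 * P[2:nf]
    }
    acc <- acc + P
  }
  freq <- (seq_len(nf) - 1L) * fs / L
  list(frequencies = freq, power = acc / length(starts),
       nSegments = length(starts))
}

# Trapezoidal integral of a sampled spectrum over [lo, hi], with linearly
# interpolated band-edge ordinates so band limits need not fall on the grid.
.bandPower <- function(freq, power, lo, hi) {
  if (hi <= freq[1] || lo >= freq[length(freq)]) return(0)
  lo <- max(lo, freq[1]); hi <- min(hi, freq[length(freq)])
  inner <- freq > lo & freq < hi
  f <- c(lo, freq[inner], hi)
  p <- c(approx(freq, power, xout = lo)$y, power[inner],
         approx(freq, power, xout = hi)$y)
  pracma::trapz(f, p)
}

# Centered moving average over a time window (seconds) on irregularly
# sampled values; O(n) via cumulative sums.
.movingAverageTime <- function(t, v, windowS) {
  if (windowS <= 0) return(v)
  half <- windowS / 2
  cs <- c(0, cumsum(v))
  j1 <- findInterval(t - half, t, left.open = TRUE) + 1L
  j2 <- findInterval(t + half, t)
  (cs[j2 + 1L] - cs[j1]) / (j2 - j1 + 1L)
}

# Linear detrend (returns residuals of ls line fit on index).
.detrendLinear <- function(x) {
  n <- length(x)
  t <- seq_len(n)
  fit <- lm.fit(cbind(1, t), x)
  x - fit$fitted.values
}

# Derive a stream of child seeds (< 2^31) from a base seed.
.childSeeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
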