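#' Poincare-plot dispersion indices
#'
#' SD1 (dispersion perpendicular to the identity line, short-term
#' variability) and SD2 (dispersion along it, long-term variability).
#' Conventions are matched so that two algebraic identities hold exactly:
#' `SD1 = RMSSD / sqrt(2)` (second-moment convention on the successive
#' differences) and `SD1^2 + SD2^2 = 2 * SDNN^2` (SDNN with n-1). A
#' negative SD2 radicand (possible by rounding on near-degenerate series)
#' is clamped to zero with a warning.
#'
#' @param rr an [RRSeries-class] segment or numeric intervals (ms), >= 3.
#' @return one-row data.frame with `sd1`, `sd2`, `sd1_sd2` (ratio, `NA`
#'   when SD2 = 0).
#' @export
poincareSd <- function(rr) {
  v <- .rrValues(rr)
  .stopIfNot(length(v) >= 3, "need at least 3 intervals")
  d <- diff(v)
  sd1 <- sqrt(mean(d^2) / 2)
  rad <- 2 * var(v) - sd1^2
  if (rad < 0) {
    if (rad < -1e-9 * max(1, var(v)))
      warning("negative SD2 radicand clamped to zero")
    rad <- 0
  }
  sd2 <- sqrt(rad)
  data.frame(sd1 = sd1, sd2 = sd2,
             sd1_sd2 = if (sd2 > 0) sd1 / sd2 else NA_real_)
}

# Chebyshev-distance match matrix of m-length templates; n x n logical.
# Templates start at positions 1..nTemplates.
.templateMatches <- function(x, m, r, nTemplates) {
  D <- matrix(0, nTemplates, nTemplates)
  for (k in seq_len(m)) {
    xk <- x[(k - 1L) + seq_len(nTemplates)]
    D <- pmax(D, abs(outer(xk, xk, "-")))
  }
  D <= r
}

#' Approximate entropy
#'
#' `ApEn(m, r) = Phi_m - Phi_(m+1)` with self-matches included and
#' Chebyshev template distance; `r = entropyRFactor * SD` of the segment.
#' A constant segment (zero SD) returns 0 with a `degenerate` flag, by
#' convention.
#'
#' @param rr an [RRSeries-class] segment or numeric intervals (ms).
#' @param settings an [analysisSettings()] list (uses `entropyM`,
#'   `entropyRFactor`).
#' @return list with `apen`, `r`, `degenerate`.
#' @export
approximateEntropy <- function(rr, settings = analysisSettings()) {
  x <- .rrValues(rr)
  m <- settings$entropyM
  .stopIfNot(length(x) >= m + 2, "segment too short for ApEn")
  if (length(x) < 50)
    warning("fewer than 50 intervals; ApEn estimate is unreliable")
  s <- sd(x)
  if (s < .Machine$double.eps)
    return(list(apen = 0, r = 0, degenerate = TRUE))
  r <- settings$entropyRFactor * s
  phi <- function(mm) {
    nT <- length(x) - mm + 1L
    M <- .templateMatches(x, mm, r, nT)
    mean(log(rowSums(M) / nT))
  }
  list(apen = phi(m) - phi(m + 1L), r = r, degenerate = FALSE)
}

#' Sample entropy
#'
#' `SampEn(m, r) = -ln(A / B)` where `B` counts m-length and `A`
#' (m+1)-length Chebyshev template matches over ordered pairs of distinct
#' templates (self-matches excluded); both lengths use the same `N - m`
#' templates. `r = entropyRFactor * SD`. Returns `NA` (with warning) when
#' `A = 0`; a constant segment returns 0 with a `degenerate` flag.
#'
#' @inheritParams approximateEntropy
#' @return list with `sampen`, `r`, `degenerate`.
#' @export
sampleEntropy <- function(rr, settings = analysisSettings()) {
  x <- .rrValues(rr)
  m <- settings$entropyM
  .stopIfNot(length(x) >= m + 2, "segment too short for SampEn")
  if (length(x) < 50)
    warning("fewer than 50 intervals; SampEn estimate is unreliable")
  s <- sd(x)
  if (s < .Machine$double.eps)
    return(list(sampen = 0, r = 0, degenerate = TRUE))
  r <- settings$entropyRFactor * s
  nT <- length(x) - m            # same template count for both lengths
  Mb <- .templateMatches(x, m, r, nT)
  Ma <- .templateMatches(x, m + 1L, r, nT)
  B <- (sum(Mb) - nT) / 2        # unordered distinct pairs
  A <- (sum(Ma) - nT) / 2
  if (B == 0 || A == 0) {
    warning("no template matches; SampEn undefined")
    return(list(sampen = NA_real_, r = r, degenerate = FALSE))
  }
  list(sampen = -log(A / B), r = r, degenerate = FALSE)
}

#' Short-term DFA scaling exponent alpha1
#'
#' Detrended fluctuation analysis over box sizes 4-11 beats: the
#' mean-centered series is integrated; for each box size the integrated
#' profile is split into non-overlapping boxes (trailing partial box
#' dropped), a least-squares line is removed per box, and `F(n)` is the RMS
#' residual over all covered points. `alpha1` is the slope of
#' `log10 F(n)` on `log10 n`. Expected calibration: ~0.5 for white noise,
#' ~1.0 for 1/f-like series, ~1.5 for Brownian noise.
#'
#' @param rr an [RRSeries-class] segment or numeric intervals (ms).
#' @param settings an [analysisSettings()] list (uses `dfaRange`).
#' @return list with `alpha1`, `boxSizes`, `fluctuation`.
#' @export
dfaAlpha1 <- function(rr, settings = analysisSettings()) {
  x <- .rrValues(rr)
  boxes <- seq(settings$dfaRange[1], settings$dfaRange[2])
  .stopIfNot(length(x) >= 2 * max(boxes),
             sprintf("segment shorter than twice the maximum box size (%d)",
                     2 * max(boxes)))
  if (length(x) < 100)
    warning("fewer than 100 intervals; alpha1 estimate is unreliable")
  y <- cumsum(x - mean(x))
  Fn <- vapply(boxes, function(n) {
    nbox <- length(y) %/% n
    Y <- matrix(y[seq_len(nbox * n)], nrow = n)
    t <- seq_len(n)
    X <- cbind(1, t)
    # residual-maker applied to all boxes at once
    R <- Y - X %*% solve(crossprod(X), crossprod(X, Y))
    sqrt(mean(R^2))
  }, numeric(1))
  ok <- Fn > 0
  .stopIfNot(sum(ok) >= 2, "degenerate series: zero fluctuation")
  fit <- lm.fit(cbind(1, log10(boxes[ok])), log10(Fn[ok]))
  a1 <- fit$coefficients[2]
  if (is.na(a1) || a1 < 0 || a1 > 2)
    warning("alpha1 outside the typical [0, 2] range")
  list(alpha1 = unname(a1), boxSizes = boxes, fluctuation = Fn)
}

#' All HRV indices for one 5-min segment
#'
#' Convenience wrapper computing the full index record for one
#' subject-phase: time domain, frequency domain (including EDR via the
#' R-amplitude path when `beats` is supplied, else the RR fallback) and
#' non-linear indices. Undefined values propagate as `NA`, never as zeros.
#'
#' @param rr an [RRSeries-class] segment.
#' @param settings an [analysisSettings()] list.
#' @param beats optional [BeatSeries-class] restricted to the same segment,
#'   enabling the R-amplitude EDR path.
#' @return one-row data.frame with all index columns.
#' @export
computeHrvIndices <- function(rr, settings = analysisSettings(),
                              beats = NULL) {
  .stopIfNot(is(rr, "RRSeries"), "rr must be an RRSeries")
  ti <- computeTimeIndices(rr)
  tach <- resampleRR(rr, settings)
  spec <- computePsdWelch(tach, settings)
  fi <- computeFreqIndices(spec, settings)
  edr <- if (!is.null(beats)) estimateEdr(beats, settings) else
    estimateEdr(rr, settings)
  fi$edr <- edr$edr
  pc <- poincareSd(rr)
  ap <- approximateEntropy(rr, settings)
  se <- sampleEntropy(rr, settings)
  a1 <- tryCatch(dfaAlpha1(rr, settings),
                 error = function(e) list(alpha1 = NA_real_))
  cbind(ti, fi, pc,
        data.frame(apen = ap$apen, sampen = se$sampen, alpha1 = a1$alpha1))
}
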